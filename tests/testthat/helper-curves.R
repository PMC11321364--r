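# printed calibration relations used throughout the tests
light_curve <- function() calibration_curve(109, -25.95, "light")
moderate_curve <- function() calibration_curve(109.2, -32.69, "moderate")
dark_curve <- function() calibration_curve(110.6, -50.31, "dark")

# closed-form OLS oracle, independent of lm()
ols_oracle <- function(x, y) {
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  c(intercept = mean(y) - b * mean(x), slope = b)
}

# standard error of a mean
se_mean <- function(x) stats::sd(x) / sqrt(length(x))
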