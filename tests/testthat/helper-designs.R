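# Shared fixtures: the two reference surveillance designs and the frozen
# days-to-detect columns of the reference scenario tables.

myo_design <- function() sccs_design(relative_incidence = 3)
vitt_design <- function() sccs_design(relative_incidence = 5)

extdata <- function(file) {
  system.file("extdata", file, package = "sccspool", mustWork = TRUE)
}

table1_days <- c(94, 158, 268, 314, 997, 1181, 1380, 1725, 2620, 8672,
                 59, 39, 37)
table2_days <- c(85, 163, 243, 274, 888, 1086, 1395, 1913, 3024, 8033,
                 56, 36, 34)
table3_rare_days <- c(940, 1573, 2674, 3137, 9964, 11810, 13796, 17242,
                      26199, 86716, 589, 516, 362)
table3_common_days <- c(10, 16, 27, 32, 100, 119, 138, 173, 262, 868,
                        6, 6, 4)

# Independent oracle for upper-tail binomial probabilities: closed-form CDF,
# never the package's own log-space summation.
tail_oracle <- function(k, n, p) pbinom(k - 1, n, p, lower.tail = FALSE)
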