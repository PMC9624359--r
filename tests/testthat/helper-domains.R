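# Four-point toy domain used across the worked examples:
# x=(1,2), y=(-2,4), p=(0,5), q=(3,1) labelled 1..4.
toy_domain <- function() {
  food_domain(rbind(c(1, 2), c(-2, 4), c(0, 5), c(3, 1)))
}

# seeded random domain with continuous (tie-free, a.s.) coordinates
random_domain <- function(n, seed, d = 2) {
  set.seed(seed)
  food_domain(matrix(rnorm(n * d, sd = 5), ncol = d))
}

# strictly ascending random vector of length m
random_ascending <- function(m, scale = 1) {
  cumsum(runif(m, 0.05, 1)) * scale + runif(1, -5, 5)
}

# independent order-statistic oracle: explicit full sort of the distance list
oracle_relative_min <- function(center, subset, k, D) {
  dv <- D$values[as.character(center), as.character(subset)]
  unname(sort(dv)[k])
}

withr_tempfile <- function(ext) tempfile(fileext = ext)
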