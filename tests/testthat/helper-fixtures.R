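# Shared in-code fixtures and independent brute-force oracles.

make_context <- function(...) {
  economic_context(
    inflation_index = c("2016" = 263.1, "2017" = 272.5, "2018" = 278.1),
    ...
  )
}

# small costbook: two tiers for one test, binned entries across all five bins
make_costbook <- function(context = NULL) {
  costbook(tibble::tibble(
    test_name = c("alpha seq", "alpha seq", "beta seq", "gamma panel",
                  "bin10a", "bin10b", "bin20a", "bin30a", "bin40a",
                  "bin41a", "bin41b", "bin41c"),
    test_class = c("single_gene", "single_gene", "single_gene", "gene_panel",
                   rep("single_gene", 8)),
    amplicon_count = c(NA, NA, NA, NA, 3L, 10L, 11L, 25L, 36L, 45L, 80L, 120L),
    cost_gbp = c(420, 500, 320, 1100, 100, 200, 600, 700, 750, 800, 900, 1000),
    price_year = 2018L,
    tier = c("scotland_lab", "uk_lab", "uk_lab", "scotland_lab",
             rep("scotland_lab", 8))
  ), context = context)
}

random_costbook <- function(n = 30L) {
  costbook(tibble::tibble(
    test_name = sprintf("rnd-%03d", seq_len(n)),
    test_class = sample(c("single_gene", "gene_panel", "epigenetic"), n, TRUE),
    amplicon_count = ifelse(stats::runif(n) < 0.7,
                            sample(1:100, n, TRUE), NA_integer_),
    cost_gbp = round(stats::runif(n, 50, 3000), 2),
    price_year = 2018L,
    tier = sample(c("scotland_lab", "uk_lab"), n, TRUE)
  ))
}

# independent type-7 quantile: direct order-statistic interpolation
oracle_quantile7 <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p
  lo <- floor(h)
  x[lo + 1] + (h - lo) * (x[pmin(lo + 2, length(x))] - x[lo + 1])
}

oracle_summary <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  list(
    n = n, mean = m,
    sd = if (n > 1) sqrt(sum((x - m)^2) / (n - 1)) else 0,
    median = oracle_quantile7(x, 0.5),
    min = min(x), max = max(x),
    iqr = oracle_quantile7(x, 0.75) - oracle_quantile7(x, 0.25)
  )
}

oracle_tukey <- function(x, k = 1.5) {
  q1 <- oracle_quantile7(x, 0.25)
  q3 <- oracle_quantile7(x, 0.75)
  which(x < q1 - k * (q3 - q1) | x > q3 + k * (q3 - q1))
}
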