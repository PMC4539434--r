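# shared fixtures, all built in code

# curves lying exactly in the Fourier span: combinations of sin/cos at the
# fundamental frequency solve x'' + omega^2 x = 0 exactly
inspan_curves <- function(n = 2, n_pos = 200, seed = 1) {
  tt <- seq(0, 100, length.out = n_pos)
  om <- 2 * pi / 100
  ab <- with_test_seed(seed, matrix(stats::rnorm(2 * n), n, 2))
  lapply(seq_len(n), function(i)
    expression_curve("inspan", sprintf("s%02d", i), tt,
                     ab[i, 1] * sin(om * tt) + ab[i, 2] * cos(om * tt)))
}

with_test_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# joint relative L2 error of fitted coefficient functions on the central
# 80% of [0, 100]
coeff_rel_err <- function(coeffs, w0_true = default_w0, w1_true = default_w1) {
  tc <- seq(10, 90, length.out = 401)
  w <- eval_coefficients(coeffs, tc)
  sqrt(sum((w$w0 - w0_true(tc))^2 + (w$w1 - w1_true(tc))^2) /
         sum(w0_true(tc)^2 + w1_true(tc)^2))
}

# write a small long-TSV coverage fixture and its labels file; returns paths
# (plain tempfile dir: must outlive this helper's frame)
write_coverage_fixture <- function(dir = {
  d <- tempfile("covfix"); dir.create(d); d
}) {
  cov <- file.path(dir, "coverage.tsv")
  lab <- file.path(dir, "labels.tsv")
  d <- expand.grid(position = 101:116, sample_id = c("sampA", "sampB"),
                   stringsAsFactors = FALSE)
  d$gene_id <- "geneX"
  d$count <- rep(c(0:7, 7:0), 2) * ifelse(d$sample_id == "sampA", 1, 3)
  write.table(d[, c("gene_id", "sample_id", "position", "count")], cov,
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(sample_id = c("sampA", "sampB"),
                         group = c("normal", "tumor")),
              lab, sep = "\t", quote = FALSE, row.names = FALSE)
  list(coverage = cov, labels = lab)
}
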