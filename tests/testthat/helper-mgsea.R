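# Shared fixture builders and independent reference implementations.

# score table whose ranking by `scores` puts `genes` in the given order
table_from_order <- function(genes, feature = "f1") {
  out <- tibble::tibble(gene = genes)
  out[[feature]] <- rev(seq_along(genes)) / length(genes)
  out
}

# random score table over n genes and the given platforms
random_score_table <- function(n, platforms = c("x1", "x2"), seed = 1) {
  withr::with_seed(seed, {
    out <- tibble::tibble(gene = sprintf("g%04d", seq_len(n)))
    for (p in platforms) out[[p]] <- stats::runif(n)
    out
  })
}

# brute-force joint walk: explicit union of top-x prefixes at every rank
brute_joint_hits <- function(orderings, members) {
  N <- length(orderings[[1]])
  vapply(seq_len(N), function(x) {
    un <- unique(unlist(lapply(orderings, function(o) o[seq_len(x)])))
    sum(un %in% members)
  }, numeric(1))
}

# reference one-sided MWU p-value via stats::wilcox.test
wilcox_greater_p <- function(a, b, exact = FALSE) {
  suppressWarnings(
    stats::wilcox.test(a, b, alternative = "greater", exact = exact, correct = TRUE)$p.value
  )
}

write_tmp_gmt <- function(lines) {
  f <- withr::local_tempfile(fileext = ".gmt", .local_envir = parent.frame())
  writeLines(lines, f)
  f
}
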