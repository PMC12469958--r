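# Shared fixtures and independent oracles used across the suite.

# A small cohort spec that keeps unit tests fast while preserving the
# generator's structure (two classes, subclones, slides, non-tumor band).
tiny_spec <- function(seed = 1L, ...) {
  args <- utils::modifyList(
    list(n_patients_per_class = c(RecPro = 5L, NED = 5L),
         spectra_per_patient = 60L, n_features = 80L,
         n_signal_features = 8L, slide_count = 3L, seed = seed),
    list(...))
  do.call(cohort_spec, args)
}

# cache expensive fixtures across test files within one run
.fixture_env <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_env))
    assign(key, expr, envir = .fixture_env)
  get(key, envir = .fixture_env)
}

tiny_cohort <- function() cached("tiny_cohort", generate_cohort(tiny_spec()))

# --- independent oracles ---

# erosion-then-dilation top-hat by brute-force sliding windows
brute_tophat <- function(x, w) {
  n <- length(x); h <- (w - 1) / 2
  win <- function(i) max(1, i - h):min(n, i + h)
  ero <- vapply(seq_len(n), function(i) min(x[win(i)]), numeric(1))
  dil <- vapply(seq_len(n), function(i) max(ero[win(i)]), numeric(1))
  x - dil
}

# exhaustive pairwise AUC
brute_auc <- function(a, b) {
  tot <- 0
  for (ai in a) for (bi in b) tot <- tot + (ai > bi) + 0.5 * (ai == bi)
  tot / (length(a) * length(b))
}

# exact two-sided rank-sum p-value by full enumeration of group assignments
enum_ranksum <- function(a, b) {
  pooled <- c(a, b); n1 <- length(a)
  r <- rank(pooled)
  U_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * length(b) / 2
  combs <- utils::combn(length(pooled), n1)
  U_all <- apply(combs, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  mean(abs(U_all - mu) >= abs(U_obs - mu))
}

# Benjamini-Hochberg step-up by definition
brute_bh <- function(p) {
  m <- length(p); o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m); out[o] <- pmin(1, adj)
  out
}
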