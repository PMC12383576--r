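# Shared fixtures and independent oracles, all built in code.

# Small labelled dataset with one strongly informative continuous feature,
# one weak one, and a categorical flag.
tiny_dataset <- function(n = 60, seed = 42) {
  set.seed(seed)
  y <- rep(c(0L, 1L), length.out = n)
  x1 <- rnorm(n, mean = ifelse(y == 1, 3, 0))
  x2 <- rnorm(n)
  flag <- rbinom(n, 1, ifelse(y == 1, 0.7, 0.2))
  X <- cbind(x1 = x1, x2 = x2, flag = flag)
  schema <- data.frame(
    name = c("x1", "x2", "flag"),
    kind = c("continuous", "continuous", "categorical"),
    discretize = c(TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
  tabular_dataset(X, y, schema)
}

# Unnormalized Gini impurity of a node with n samples, `pos` positives.
gini_term_oracle <- function(n, pos) {
  if (n <= 0) return(0)
  n - (pos^2 + (n - pos)^2) / n
}

# Exhaustive search over all midpoint candidates for the Gini-optimal
# binary split (ties -> smallest threshold). Independent of the tree grower.
best_split_oracle <- function(x, y, min_leaf = 1) {
  xs <- sort(unique(x))
  if (length(xs) < 2) return(NULL)
  cands <- xs[-length(xs)] + diff(xs) / 2
  best <- NULL
  for (thr in cands) {
    left <- x <= thr
    nl <- sum(left); nr <- sum(!left)
    if (nl < min_leaf || nr < min_leaf) next
    imp <- gini_term_oracle(nl, sum(y[left])) +
           gini_term_oracle(nr, sum(y[!left]))
    if (is.null(best) || imp < best$imp - 1e-9) best <- list(thr = thr, imp = imp)
  }
  best
}

# Interval index by linear scan of the right-closed interval conditions
# theta[k-1] < x <= theta[k] with virtual +-Inf boundaries.
scan_interval_oracle <- function(thresholds, x) {
  ext <- c(-Inf, thresholds, Inf)
  for (k in seq_len(length(ext) - 1)) {
    if (ext[k] < x && x <= ext[k + 1]) return(k)
  }
  stop("no interval found")
}

# Interval index via the summation form: sum over k of k * 1[x in I(k)].
sum_interval_oracle <- function(thresholds, x) {
  ext <- c(-Inf, thresholds, Inf)
  K <- length(thresholds) + 1
  sum(vapply(seq_len(K), function(k)
    k * as.numeric(ext[k] < x && x <= ext[k + 1]), numeric(1)))
}

# Probability-of-correct-ranking (Mann-Whitney) AUROC estimator.
auroc_mw_oracle <- function(y, s) {
  pos <- s[y == 1]; neg <- s[y == 0]
  cmp <- outer(pos, neg, ">") + 0.5 * outer(pos, neg, "==")
  mean(cmp)
}

make_view <- function(tag, m) {
  structure(list(tag = tag, matrix = m), class = "feature_view")
}
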