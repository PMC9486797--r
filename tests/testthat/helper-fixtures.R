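# Shared fixtures built in code.

# small well-conditioned panel: K cells, a discriminating CpG per cell
# plus shared background CpGs
tiny_panel <- function(n_background = 6, sd = 0.03) {
  cells <- c("CD4T", "CD8T", "Bcell", "NK", "Mono", "Neu")
  K <- length(cells)
  J <- K + n_background
  means <- matrix(0.5, J, K)
  for (k in seq_len(K)) {
    means[k, ] <- 0.85
    means[k, k] <- 0.1
  }
  set.seed(99)
  for (j in (K + 1):J) means[j, ] <- runif(K, 0.2, 0.8)
  df <- data.frame(
    cpg_id = rep(sprintf("cgs%05d", seq_len(J)), K),
    cell_type = rep(cells, each = J),
    mean = as.vector(means),
    sd = sd,
    is_index = FALSE)
  reference_panel(df)
}

# brute-force BH step-up used as an independent oracle
bh_brute_force <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- rep(NA_real_, n)
  prev <- Inf
  for (i in n:1) {
    val <- min(prev, p[o[i]] * n / i, 1)
    adj[o[i]] <- val
    prev <- val
  }
  adj
}

# brute-force AUC over all positive-negative pairs with half credit ties
auc_brute_force <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}
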