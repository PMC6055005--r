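# shared fixture builders; everything generated in code, no files needed

# small expression matrix with dimnames
toy_expression <- function(nr = 6, nc = 4, seed = 42) {
  set.seed(seed)
  matrix(round(stats::rnorm(nr * nc), 4), nr, nc,
         dimnames = list(sprintf("tf%02d", seq_len(nr)),
                         sprintf("c%02d", seq_len(nc))))
}

# catalog with two clusters x two signature categories, fully deterministic
toy_catalog <- function() {
  tfs <- sprintf("tf%02d", 1:6)
  annotation_catalog(
    tf_targets = data.frame(
      tf = rep(tfs, each = 2),
      gene = sprintf("g%02d", 1:12),
      mode = rep(c("activator", "repressor"), 6)),
    tf_family = stats::setNames(rep(c("famA", "famB"), each = 3), tfs),
    tf_evidence = stats::setNames(rep("strong", 6), tfs),
    gene_categories = list(
      toy = data.frame(gene = sprintf("g%02d", 1:12),
                       category = rep(c("catA", "catB"), each = 6))))
}

toy_partition <- function() partition(sprintf("tf%02d", 1:6),
                                      rep(c("A", "B"), each = 3))

# brute-force one-tailed Fisher p by explicit table enumeration with choose()
enum_fisher_upper <- function(a, b, c, d) {
  n <- a + b + c + d
  m1 <- a + b; m2 <- a + c
  xs <- max(0, m1 + m2 - n):min(m1, m2)
  probs <- choose(m2, xs) * choose(n - m2, m1 - xs) / choose(n, m1)
  sum(probs[xs >= a])
}

# independent sum-of-squares oracle: direct double loop over points
brute_wss <- function(x, labels) {
  labs <- unique(labels)
  tot <- 0
  for (l in labs) {
    xi <- x[labels == l, , drop = FALSE]
    ctr <- colMeans(xi)
    for (i in seq_len(nrow(xi))) tot <- tot + sum((xi[i, ] - ctr)^2)
  }
  tot
}
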