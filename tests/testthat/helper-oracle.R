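# Independent naive reference implementations used as oracles. These use
# plain scalar loops and never share code with the package internals.

naive_refstats <- function(values, labels, reference) {
  c2 <- which(labels %in% reference)
  mu <- numeric(nrow(values)); sigma <- numeric(nrow(values))
  for (g in seq_len(nrow(values))) {
    v <- values[g, c2]
    mu[g] <- sum(v) / length(v)
    sigma[g] <- sqrt(sum((v - mu[g])^2) / length(v))  # population divisor
  }
  list(mu = mu, sigma = sigma)
}

naive_binarize <- function(values, labels, reference, which = "C1") {
  st <- naive_refstats(values, labels, reference)
  cols <- if (which == "C1") which(!(labels %in% reference))
          else seq_len(ncol(values))
  out <- matrix(0L, nrow(values), length(cols),
                dimnames = list(rownames(values), colnames(values)[cols]))
  for (g in seq_len(nrow(values)))
    for (j in seq_along(cols))
      if (values[g, cols[j]] > st$mu[g] + st$sigma[g]) out[g, j] <- 1L
  out
}

# triple loop: gene x sample x set
naive_scores <- function(values, labels, reference, sets,
                         mode = "measured", which = "C1") {
  bin <- naive_binarize(values, labels, reference, which)
  keep <- names(sets)[vapply(sets, function(m)
    length(intersect(m, rownames(values))) > 0L, logical(1))]
  out <- matrix(NA_real_, length(keep), ncol(bin),
                dimnames = list(keep, colnames(bin)))
  for (nm in keep) {
    measured <- intersect(sets[[nm]], rownames(values))
    denom <- if (mode == "measured") length(measured) else length(sets[[nm]])
    for (s in seq_len(ncol(bin))) {
      cnt <- 0L
      for (g in measured) cnt <- cnt + bin[g, s]
      out[nm, s] <- cnt / denom
    }
  }
  out
}

naive_mean_es_c1 <- function(values, labels, reference, sets) {
  sc <- naive_scores(values, labels, reference, sets)
  rowMeans(sc)
}

# pair-counting adjusted Rand index
naive_ari <- function(a, b) {
  n <- length(a)
  n11 <- n10 <- n01 <- n00 <- 0
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    sa <- a[i] == a[j]; sb <- b[i] == b[j]
    if (sa && sb) n11 <- n11 + 1
    else if (sa && !sb) n10 <- n10 + 1
    else if (!sa && sb) n01 <- n01 + 1
    else n00 <- n00 + 1
  }
  np <- n11 + n10 + n01 + n00
  expected <- (n11 + n10) * (n11 + n01) / np
  maximum <- ((n11 + n10) + (n11 + n01)) / 2
  if (maximum == expected) return(1)  # both partitions trivial
  (n11 - expected) / (maximum - expected)
}

# per-point silhouette a(i)/b(i), points in rows
naive_silhouette <- function(points, labels) {
  n <- nrow(points)
  d <- as.matrix(dist(points))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- setdiff(which(labels == labels[i]), i)
    if (length(own) == 0L) { s[i] <- 0; next }   # singleton convention
    a <- mean(d[i, own])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(cl) mean(d[i, labels == cl]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# random small scoring instance: <=30 genes, <=15 samples, <=5 sets
random_instance <- function(seed) {
  set.seed(seed)
  ng <- sample(4:30, 1); ns <- sample(4:15, 1); nset <- sample(1:5, 1)
  genes <- sprintf("G%02d", seq_len(ng))
  samples <- sprintf("S%02d", seq_len(ns))
  values <- matrix(round(stats::rexp(ng * ns, 1 / 5), 3), ng,
                   dimnames = list(genes, samples))
  n2 <- sample(2:(ns - 1), 1)
  labels <- sample(rep(c("ref", "qry"), c(n2, ns - n2)))
  sets <- lapply(seq_len(nset), function(i)
    sample(c(genes, sprintf("ABSENT%d", 1:3)), sample(2:8, 1)))
  names(sets) <- sprintf("SET%d", seq_len(nset))
  list(values = values, labels = labels, sets = sets)
}

toy_file <- function(name) {
  path <- system.file("extdata", name, package = "gdgse")
  if (!nzchar(path)) path <- file.path("../../inst/extdata", name)
  path
}

toy_expr_labeled <- function() {
  attach_labels(read_expression(toy_file("toy_expression.tsv")),
                toy_file("toy_labels.tsv"), reference = "normal")
}
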