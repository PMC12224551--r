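# Independent brute-force oracles. These deliberately share no code with
# the package: alignment is a hand-rolled Gotoh DP, components a plain
# BFS, mutual-best a double loop.

# Affine-gap global alignment by dynamic programming with traceback.
# A gap of length L costs go + L * ge; end gaps are penalized.
oracle_align <- function(a, b, match = 1, mismatch = -1, go = 2, ge = 1) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)  # ends in (mis)match
  X <- matrix(NEG, n + 1, m + 1)  # ends with gap in b (a char vs -)
  Y <- matrix(NEG, n + 1, m + 1)  # ends with gap in a
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- -(go + i * ge)
  for (j in seq_len(m)) Y[1, j + 1] <- -(go + j * ge)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    s <- if (av[i] == bv[j]) match else mismatch
    M[i + 1, j + 1] <- s + max(M[i, j], X[i, j], Y[i, j])
    X[i + 1, j + 1] <- max(M[i, j + 1] - go - ge, X[i, j + 1] - ge,
                           Y[i, j + 1] - go - ge)
    Y[i + 1, j + 1] <- max(M[i + 1, j] - go - ge, Y[i + 1, j] - ge,
                           X[i + 1, j] - go - ge)
  }
  score <- max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
  # traceback (ties resolved M > X > Y; identity asserted only where the
  # optimal alignment is unambiguous)
  i <- n; j <- m
  state <- which.max(c(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1]))
  cols <- 0L; matches <- 0L; aligned <- 0L
  while (i > 0 || j > 0) {
    cols <- cols + 1L
    if (state == 1L && i > 0 && j > 0) {
      s <- if (av[i] == bv[j]) match else mismatch
      if (av[i] == bv[j]) matches <- matches + 1L
      aligned <- aligned + 1L
      prev <- c(M[i, j], X[i, j], Y[i, j])
      state <- which(abs(prev + s - M[i + 1, j + 1]) < 1e-9)[1]
      i <- i - 1; j <- j - 1
    } else if (state == 2L || (j == 0 && i > 0)) {
      prev <- c(M[i, j + 1] - go - ge, X[i, j + 1] - ge,
                Y[i, j + 1] - go - ge)
      state <- which(abs(prev - X[i + 1, j + 1]) < 1e-9)[1]
      if (is.na(state)) state <- 2L
      i <- i - 1
    } else {
      prev <- c(M[i + 1, j] - go - ge, X[i + 1, j] - go - ge,
                Y[i + 1, j] - ge)
      state <- which(abs(prev - Y[i + 1, j + 1]) < 1e-9)[1]
      if (is.na(state)) state <- 3L
      j <- j - 1
    }
  }
  list(score = score, identity = matches / cols,
       coverage = aligned / min(n, m))
}

# connected components by BFS over an adjacency predicate
oracle_components <- function(nodes, linked) {
  comp <- setNames(rep(NA_integer_, length(nodes)), nodes)
  k <- 0L
  for (s in nodes) {
    if (!is.na(comp[[s]])) next
    k <- k + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[[v]])) next
      comp[[v]] <- k
      for (w in nodes) if (is.na(comp[[w]]) && linked(v, w))
        queue <- c(queue, w)
    }
  }
  comp
}

# mutual best pairs from an identity matrix (double loop)
oracle_mutual_best <- function(idm, cvm, min_id, min_cov) {
  out <- list()
  for (qa in rownames(idm)) for (tb in colnames(idm)) {
    best_a <- sort(colnames(idm)[idm[qa, ] == max(idm[qa, ])])[1]
    best_b <- sort(rownames(idm)[idm[, tb] == max(idm[, tb])])[1]
    if (best_a == tb && best_b == qa &&
        idm[qa, tb] >= min_id && cvm[qa, tb] >= min_cov)
      out[[length(out) + 1]] <- c(query = qa, target = tb)
  }
  out
}

# independent greedy centroid clustering using the oracle aligner
oracle_greedy_cluster <- function(proteins, min_id, min_cov) {
  ord <- order(-nchar(proteins$translation), proteins$genome_id,
               proteins$locus_tag, method = "radix")
  proteins <- proteins[ord, ]
  centroids <- character(); assign <- integer(nrow(proteins))
  for (i in seq_len(nrow(proteins))) {
    hit <- 0L
    for (k in seq_along(centroids)) {
      r <- oracle_align(proteins$translation[i], centroids[k])
      if (r$identity >= min_id && r$coverage >= min_cov) { hit <- k; break }
    }
    if (hit == 0L) { centroids <- c(centroids, proteins$translation[i])
                     hit <- length(centroids) }
    assign[i] <- hit
  }
  split(proteins$locus_tag, assign)
}
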