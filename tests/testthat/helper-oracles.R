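# Independent brute-force oracles, deliberately written with different
# algorithms than the package implementations: Floyd-Warshall distance and
# path counting, direct Burt formula, linear-system PageRank,
# eigendecomposition HITS, peeling k-core, all-pairs contact and dominance
# scans.

# Floyd-Warshall shortest-path distances from an adjacency matrix
oracleDistances <- function(A) {
  n <- nrow(A)
  D <- ifelse(A > 0, 1, Inf)
  diag(D) <- 0
  for (k in seq_len(n)) {
    D <- pmin(D, outer(D[, k], D[k, ], "+"))
  }
  D
}

# number of shortest paths between every pair (Floyd-Warshall style)
oraclePathCounts <- function(A) {
  n <- nrow(A)
  D <- oracleDistances(A)
  S <- matrix(0, n, n)
  S[A > 0] <- 1
  diag(S) <- 1
  for (len in 2:max(1, max(D[is.finite(D)]))) {
    idx <- which(D == len, arr.ind = TRUE)
    for (r in seq_len(nrow(idx))) {
      i <- idx[r, 1]; j <- idx[r, 2]
      mids <- which(A[i, ] > 0 & D[, j] == len - 1)
      S[i, j] <- sum(S[cbind(mids, j)])
    }
  }
  S
}

# unnormalized betweenness: pair-dependency counts, each unordered pair once
oracleBetweenness <- function(A) {
  n <- nrow(A)
  D <- oracleDistances(A)
  S <- oraclePathCounts(A)
  b <- numeric(n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    if (!is.finite(D[s, t]) || S[s, t] == 0) next
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      if (is.finite(D[s, v]) && is.finite(D[v, t]) &&
          D[s, v] + D[v, t] == D[s, t]) {
        b[v] <- b[v] + S[s, v] * S[v, t] / S[s, t]
      }
    }
  }
  b
}

# within-component closeness with (n_comp - 1) normalization, isolated -> 0
oracleCloseness <- function(A) {
  D <- oracleDistances(A)
  vapply(seq_len(nrow(A)), function(v) {
    comp <- which(is.finite(D[v, ]))
    if (length(comp) <= 1) 0 else (length(comp) - 1) / sum(D[v, comp])
  }, 0)
}

# Burt's constraint by the direct formula, p_ij = 1/degree(i); NA isolated
oracleBurt <- function(A) {
  n <- nrow(A)
  deg <- rowSums(A)
  P <- A / ifelse(deg == 0, 1, deg)
  out <- rep(NA_real_, n)
  for (i in which(deg > 0)) {
    s <- 0
    for (j in which(A[i, ] > 0)) {
      q <- setdiff(seq_len(n), c(i, j))
      s <- s + (P[i, j] + sum(P[i, q] * P[q, j]))^2
    }
    out[i] <- s
  }
  out
}

# PageRank by direct linear solve (uniform teleport, dangling mass spread)
oraclePagerank <- function(A, damping = 0.85) {
  n <- nrow(A)
  deg <- colSums(A)
  P <- A
  for (i in seq_len(n)) {
    P[, i] <- if (deg[i] == 0) 1 / n else A[, i] / deg[i]
  }
  solve(diag(n) - damping * P, rep((1 - damping) / n, n))
}

# HITS authority: projection of the uniform vector onto the top eigenspace
# of A^2 (the power-iteration limit), max-normalized
oracleAuthority <- function(A, tol = 1e-9) {
  if (sum(A) == 0) return(numeric(nrow(A)))
  e <- eigen(A, symmetric = TRUE)
  lmax <- max(abs(e$values))
  top <- which(abs(abs(e$values) - lmax) < tol * lmax)
  u <- rep(1, nrow(A))
  proj <- numeric(nrow(A))
  for (k in top) proj <- proj + sum(u * e$vectors[, k]) * e$vectors[, k]
  proj / max(proj)
}

# k-core by iterative peeling
oracleKcore <- function(A) {
  n <- nrow(A)
  core <- integer(n)
  alive <- rep(TRUE, n)
  k <- 0
  while (any(alive)) {
    repeat {
      idx <- which(alive)
      deg <- rowSums(A[idx, idx, drop = FALSE])
      low <- idx[deg <= k]
      if (length(low) == 0) break
      core[low] <- k
      alive[low] <- FALSE
      if (!any(alive)) break
    }
    k <- k + 1
  }
  core
}

# all-pairs O(n^2) contact scan over heavy atoms of a RINStructure
oracleContacts <- function(structure, cutoff = 5.0, excludeCovalent = TRUE) {
  a <- structure@atoms[!structure@atoms$isHydrogen, , drop = FALSE]
  n <- nrow(a)
  res <- list()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (a$key[i] == a$key[j]) next
    d <- sqrt((a$x[i] - a$x[j])^2 + (a$y[i] - a$y[j])^2 + (a$z[i] - a$z[j])^2)
    if (d >= cutoff) next
    if (excludeCovalent) {
      sameChain <- a$chain[i] == a$chain[j]
      pep <- sameChain &&
        ((a$elety[i] == "C" && a$elety[j] == "N") ||
         (a$elety[i] == "N" && a$elety[j] == "C")) &&
        (abs(a$resno[i] - a$resno[j]) == 1 || d < 1.8)
      ss <- a$elety[i] == "SG" && a$elety[j] == "SG" && d < 2.5
      if (pep || ss) next
    }
    ka <- min(a$key[i], a$key[j]); kb <- max(a$key[i], a$key[j])
    id <- paste(ka, kb, sep = "~")
    cls <- if (a$chainPart[i] == "main_chain" && a$chainPart[j] == "main_chain") "mc_mc"
      else if (a$chainPart[i] == "side_chain" && a$chainPart[j] == "side_chain") "sc_sc"
      else "mc_sc"
    if (is.null(res[[id]])) res[[id]] <- list(d = d, cls = cls)
    else res[[id]] <- list(d = min(d, res[[id]]$d), cls = union(res[[id]]$cls, cls))
  }
  if (length(res) == 0) {
    return(data.frame(keyA = character(0), keyB = character(0),
                      classes = character(0), minDistance = numeric(0)))
  }
  ab <- do.call(rbind, strsplit(names(res), "~", fixed = TRUE))
  out <- data.frame(
    keyA = ab[, 1], keyB = ab[, 2],
    classes = vapply(res, function(r) paste(sort(r$cls), collapse = "+"), ""),
    minDistance = vapply(res, function(r) r$d, 0),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out[order(out$keyA, out$keyB), , drop = FALSE]
}

# all-pairs dominance scan: non-dominated rows of a numeric matrix
oracleParetoFront <- function(m) {
  n <- nrow(m)
  keep <- logical(n)
  for (i in seq_len(n)) {
    dom <- FALSE
    for (j in seq_len(n)) {
      if (j == i) next
      if (all(m[j, ] >= m[i, ]) && any(m[j, ] > m[i, ])) { dom <- TRUE; break }
    }
    keep[i] <- !dom
  }
  which(keep)
}

# exact two-sided rank-sum p by enumeration over all group assignments
oracleWilcoxEnum <- function(a, b) {
  vals <- c(a, b)
  n <- length(vals); na <- length(a)
  obs <- sum(rank(vals)[seq_len(na)])
  combs <- utils::combn(n, na)
  stats <- apply(combs, 2, function(idx) sum(rank(vals)[idx]))
  mu <- na * (n + 1) / 2
  mean(abs(stats - mu) >= abs(obs - mu) - 1e-9)
}
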