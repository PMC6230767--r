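# Independent oracle implementations used to verify the package's fast
# paths. Each is written as directly as possible from the defining
# formula and shares no code with the implementation it checks.

# Quadratic-programming Smith-Waterman with affine gaps; a gap of
# length g costs open + (g - 1) * extend.
oracle_sw <- function(a, b, mat, open, extend) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  H <- matrix(0, n + 1, m + 1)
  X <- matrix(-Inf, n + 1, m + 1)  # gap in b (consume a)
  Y <- matrix(-Inf, n + 1, m + 1)  # gap in a (consume b)
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      X[i + 1, j + 1] <- max(H[i, j + 1] - open, X[i, j + 1] - extend)
      Y[i + 1, j + 1] <- max(H[i + 1, j] - open, Y[i + 1, j] - extend)
      diag <- H[i, j] + mat[A[i], B[j]]
      H[i + 1, j + 1] <- max(0, diag, X[i + 1, j + 1], Y[i + 1, j + 1])
      best <- max(best, H[i + 1, j + 1])
    }
  }
  best
}

# Literal double-centering distance correlation (Szekely-Rizzo).
oracle_dcor <- function(x, Y) {
  Y <- rbind(Y)
  m <- length(x)
  a <- abs(outer(x, x, "-"))
  b <- matrix(0, m, m)
  for (j in 1:m) for (l in 1:m) b[j, l] <- sqrt(sum((Y[, j] - Y[, l])^2))
  center <- function(M) {
    sweep(sweep(M, 1, rowMeans(M)), 2, colMeans(M)) + mean(M)
  }
  A <- center(a); B <- center(b)
  dcov2 <- mean(A * B)
  dvarx <- mean(A * A)
  dvary <- mean(B * B)
  if (dvarx <= 0 || dvary <= 0) return(0)
  sqrt(max(0, dcov2) / sqrt(dvarx * dvary))
}

# Naive UPGMA recomputing every cluster distance from scratch as the
# plain mean of original leaf-pair distances; same tie-break rule
# (lexicographically smallest pair of cluster anchors). Returns the
# cophenetic matrix.
oracle_upgma_cophenetic <- function(D) {
  labels <- rownames(D)
  n <- nrow(D)
  clusters <- lapply(seq_len(n), identity)
  C <- matrix(0, n, n, dimnames = list(labels, labels))
  while (length(clusters) > 1L) {
    k <- length(clusters)
    pr <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
    dij <- apply(pr, 1, function(p)
      mean(D[clusters[[p[1]]], clusters[[p[2]]]]))
    keys <- apply(pr, 1, function(p)
      paste(sort(c(min(labels[clusters[[p[1]]]]),
                   min(labels[clusters[[p[2]]]]))), collapse = "\r"))
    tied <- which(dij == min(dij))
    pick <- pr[tied[order(keys[tied])[1]], ]
    a <- clusters[[pick[1]]]; b <- clusters[[pick[2]]]
    C[a, b] <- C[b, a] <- min(dij)
    clusters <- c(clusters[-pick], list(c(a, b)))
  }
  C
}

# Exhaustive path-sum forward score (bits) for small profile HMMs.
# Mirrors the model conventions: begin state is M_0, insert emissions
# equal the background (odds 1), and at the last index transitions to
# both M and D lead to the end state.
oracle_forward_bits <- function(pphmm, sequence) {
  L <- pphmm$n_match_states
  x <- match(strsplit(sequence, "")[[1]], cgjtax:::AA20)
  n <- length(x)
  odds <- pphmm$match_emissions /
    matrix(pphmm$background, L, 20, byrow = TRUE)
  tr <- pphmm$transitions
  rec <- function(type, k, i) {
    total <- 0
    r <- k + 1L
    if (k == L) {
      if (i == n) {
        total <- total + switch(type,
                                M = tr[r, "MM"] + tr[r, "MD"],
                                I = tr[r, "IM"],
                                D = tr[r, "DM"] + tr[r, "DD"])
      }
      if (type == "M" && i < n) {
        total <- total + tr[r, "MI"] * rec("I", k, i + 1)
      }
      if (type == "I" && i < n) {
        total <- total + tr[r, "II"] * rec("I", k, i + 1)
      }
      return(total)
    }
    if (type == "M") {
      if (i < n) {
        total <- total + tr[r, "MM"] * odds[k + 1, x[i + 1]] * rec("M", k + 1, i + 1)
        total <- total + tr[r, "MI"] * rec("I", k, i + 1)
      }
      total <- total + tr[r, "MD"] * rec("D", k + 1, i)
    } else if (type == "I") {
      if (i < n) {
        total <- total + tr[r, "IM"] * odds[k + 1, x[i + 1]] * rec("M", k + 1, i + 1)
        total <- total + tr[r, "II"] * rec("I", k, i + 1)
      }
    } else {
      if (i < n) {
        total <- total + tr[r, "DM"] * odds[k + 1, x[i + 1]] * rec("M", k + 1, i + 1)
      }
      total <- total + tr[r, "DD"] * rec("D", k + 1, i)
    }
    total
  }
  unname(log2(rec("M", 0L, 0L)))
}

# Elementwise generalized Jaccard, written as an explicit loop.
oracle_gj <- function(a, b) {
  num <- 0; den <- 0
  for (i in seq_along(a)) {
    num <- num + min(a[i], b[i])
    den <- den + max(a[i], b[i])
  }
  if (den == 0) 0 else num / den
}

# Plug-in MI oracle on explicit 2x2 counts.
oracle_mi <- function(labels, presence) {
  n <- length(labels)
  mi <- 0
  for (l in unique(labels)) {
    for (p in unique(presence)) {
      pxy <- sum(labels == l & presence == p) / n
      if (pxy > 0) {
        mi <- mi + pxy * log2(pxy / (sum(labels == l) / n *
                                       sum(presence == p) / n))
      }
    }
  }
  mi
}

# All permutations of 1..n (n! rows), for order-invariance checks.
combinat_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- combinat_perms(n - 1)
  out <- matrix(0L, 0, n)
  for (k in 1:n) {
    out <- rbind(out, cbind(k, sub + (sub >= k)))
  }
  out
}
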