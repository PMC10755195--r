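# Independent brute-force oracles used across the suite. These stay
# deliberately naive (loops, enumeration) and share no code with the
# implementations they check.

randomGM <- function(n, m, missingRate = 0, seed = 1) {
  set.seed(seed)
  calls <- matrix(sample(0:2, n * m, replace = TRUE), n, m)
  if (missingRate > 0)
    calls[matrix(runif(n * m) < missingRate, n, m)] <- -1L
  storage.mode(calls) <- "integer"
  rownames(calls) <- paste0("S", seq_len(n))
  GenotypeMatrix(calls)
}

naiveAlleleSharing <- function(cl) {
  n <- nrow(cl)
  D <- matrix(0, n, n, dimnames = list(rownames(cl), rownames(cl)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    ok <- cl[i, ] >= 0 & cl[j, ] >= 0
    D[i, j] <- mean(abs(cl[i, ok] - cl[j, ok]) / 2)
  }
  D
}

naiveModifiedRogers <- function(cl) {
  n <- nrow(cl)
  D <- matrix(0, n, n, dimnames = list(rownames(cl), rownames(cl)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    ok <- cl[i, ] >= 0 & cl[j, ] >= 0
    xi <- cl[i, ok] / 2; xj <- cl[j, ok] / 2
    D[i, j] <- sqrt(sum((xi - xj)^2) / sum(ok))
  }
  D
}

# Naive ward.D2 agglomeration by the Lance-Williams update on squared
# distances; returns merge heights and the partition after each merge.
naiveWardD2 <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  active <- seq_len(n)
  members <- lapply(seq_len(n), identity)
  sizes <- rep(1, n)
  heights <- numeric(0)
  partitions <- list()
  Cur <- D
  diag(Cur) <- Inf
  repeat {
    if (length(active) == 1L) break
    sub <- Cur[active, active, drop = FALSE]
    ij <- arrayInd(which.min(sub), dim(sub))
    a <- active[min(ij)]; b <- active[max(ij)]
    h <- Cur[a, b]
    heights <- c(heights, h)
    newMembers <- c(members[[a]], members[[b]])
    for (k in setdiff(active, c(a, b))) {
      na <- sizes[a]; nb <- sizes[b]; nk <- sizes[k]
      d2 <- ((na + nk) * Cur[a, k]^2 + (nb + nk) * Cur[b, k]^2 -
               nk * Cur[a, b]^2) / (na + nb + nk)
      Cur[a, k] <- Cur[k, a] <- sqrt(d2)
    }
    sizes[a] <- sizes[a] + sizes[b]
    members[[a]] <- newMembers
    active <- setdiff(active, b)
    partitions[[length(partitions) + 1L]] <-
      lapply(active, function(x) sort(members[[x]]))
  }
  list(heights = heights, partitions = partitions)
}

partitionKey <- function(parts) {
  paste(sort(vapply(parts, function(p) paste(p, collapse = ","),
                    character(1))), collapse = "|")
}

hclustPartitionKey <- function(hc, k) {
  grp <- cutree(hc, k = k)
  partitionKey(lapply(unique(grp), function(g) sort(which(grp == g))))
}

naiveAN <- function(selected, D) {
  vals <- vapply(selected, function(i)
    min(D[i, setdiff(selected, i)]), numeric(1))
  mean(vals)
}
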