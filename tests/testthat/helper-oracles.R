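## Independent brute-force oracles for the texture-matrix builders.
## These deliberately use naive elementwise loops (no shared code with the
## package internals beyond the direction/offset definitions, which are
## re-derived here from scratch).

oracle_dirs13 <- local({
  d <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  d <- d[rowSums(abs(d)) > 0, ]
  keep <- logical(nrow(d))
  seen <- character()
  for (r in seq_len(nrow(d))) {
    k1 <- paste(d[r, ], collapse = ",")
    k2 <- paste(-d[r, ], collapse = ",")
    if (!(k1 %in% seen) && !(k2 %in% seen)) { keep[r] <- TRUE; seen <- c(seen, k1) }
  }
  d[keep, , drop = FALSE]
})

oracle_offs26 <- local({
  d <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  d[rowSums(abs(d)) > 0, , drop = FALSE]
})

## q: integer label array, 0 outside mask
oracle_glcm <- function(q, G) {
  dm <- dim(q)
  M <- matrix(0, G, G)
  for (i in seq_len(dm[1])) for (j in seq_len(dm[2])) for (k in seq_len(dm[3])) {
    a <- q[i, j, k]
    if (a == 0) next
    for (r in seq_len(nrow(oracle_offs26))) {
      d <- oracle_offs26[r, ]
      if (sum(abs(d)) > 0 && max(abs(d)) == 1 && sum(d != 0) >= 1) {
        ii <- i + d[1]; jj <- j + d[2]; kk <- k + d[3]
        if (ii >= 1 && ii <= dm[1] && jj >= 1 && jj <= dm[2] &&
            kk >= 1 && kk <= dm[3]) {
          b <- q[ii, jj, kk]
          if (b > 0) M[a, b] <- M[a, b] + 1
        }
      }
    }
  }
  M   # counts each ordered pair once per direction = symmetrised matrix
}

oracle_glrlm <- function(q, G) {
  dm <- dim(q)
  runs <- list()
  for (r in seq_len(nrow(oracle_dirs13))) {
    d <- oracle_dirs13[r, ]
    for (i in seq_len(dm[1])) for (j in seq_len(dm[2])) for (k in seq_len(dm[3])) {
      a <- q[i, j, k]
      if (a == 0) next
      ## run start: predecessor missing or different
      pi_ <- i - d[1]; pj <- j - d[2]; pk <- k - d[3]
      prev <- if (pi_ >= 1 && pi_ <= dm[1] && pj >= 1 && pj <= dm[2] &&
                  pk >= 1 && pk <= dm[3]) q[pi_, pj, pk] else 0L
      if (prev == a) next
      len <- 1
      ci <- i + d[1]; cj <- j + d[2]; ck <- k + d[3]
      while (ci >= 1 && ci <= dm[1] && cj >= 1 && cj <= dm[2] &&
             ck >= 1 && ck <= dm[3] && q[ci, cj, ck] == a) {
        len <- len + 1
        ci <- ci + d[1]; cj <- cj + d[2]; ck <- ck + d[3]
      }
      runs[[length(runs) + 1]] <- c(a, len)
    }
  }
  runs <- do.call(rbind, runs)
  R <- matrix(0, G, max(runs[, 2]))
  for (r in seq_len(nrow(runs)))
    R[runs[r, 1], runs[r, 2]] <- R[runs[r, 1], runs[r, 2]] + 1
  R
}

## recursive-stack flood fill, 26-connectivity, per level
oracle_glszm <- function(q, G) {
  dm <- dim(q)
  visited <- array(FALSE, dm)
  zones <- list()
  for (i in seq_len(dm[1])) for (j in seq_len(dm[2])) for (k in seq_len(dm[3])) {
    a <- q[i, j, k]
    if (a == 0 || visited[i, j, k]) next
    size <- 0
    stack <- list(c(i, j, k))
    visited[i, j, k] <- TRUE
    while (length(stack)) {
      v <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      size <- size + 1
      for (r in seq_len(nrow(oracle_offs26))) {
        w <- v + oracle_offs26[r, ]
        if (all(w >= 1) && all(w <= dm) && !visited[w[1], w[2], w[3]] &&
            q[w[1], w[2], w[3]] == a) {
          visited[w[1], w[2], w[3]] <- TRUE
          stack[[length(stack) + 1]] <- w
        }
      }
    }
    zones[[length(zones) + 1]] <- c(a, size)
  }
  zones <- do.call(rbind, zones)
  Z <- matrix(0, G, max(zones[, 2]))
  for (r in seq_len(nrow(zones)))
    Z[zones[r, 1], zones[r, 2]] <- Z[zones[r, 1], zones[r, 2]] + 1
  Z
}

oracle_ngtdm <- function(q, G) {
  dm <- dim(q)
  s <- numeric(G); cnt <- integer(G); n <- 0
  for (i in seq_len(dm[1])) for (j in seq_len(dm[2])) for (k in seq_len(dm[3])) {
    a <- q[i, j, k]
    if (a == 0) next
    nb <- c()
    for (r in seq_len(nrow(oracle_offs26))) {
      w <- c(i, j, k) + oracle_offs26[r, ]
      if (all(w >= 1) && all(w <= dm) && q[w[1], w[2], w[3]] > 0)
        nb <- c(nb, q[w[1], w[2], w[3]])
    }
    if (length(nb) == 0) next
    n <- n + 1
    cnt[a] <- cnt[a] + 1L
    s[a] <- s[a] + abs(a - mean(nb))
  }
  list(s = s, p = if (n > 0) cnt / n else numeric(G), n = n)
}

## random quantised VOI on a small grid: irregular mask + labels
random_qvoi <- function(dim3 = c(6, 6, 6), G = 4, p_mask = 0.7) {
  m <- array(runif(prod(dim3)) < p_mask, dim3)
  if (!any(m)) m[1, 1, 1] <- TRUE
  lab <- array(0L, dim3)
  lab[m] <- sample.int(G, sum(m), replace = TRUE)
  structure(list(labels = lab, G = as.integer(G),
                 source_stats = c(min = 0, max = 1)),
            class = "quantised_voi")
}

## hard-edged sphere phantom helper used across test files
sphere_mask <- function(dm, ctr, radius_vox) {
  ax <- lapply(1:3, function(a) seq_len(dm[a]) - ctr[a])
  outer(outer(ax[[1]]^2, ax[[2]]^2, `+`), ax[[3]]^2, `+`) <= radius_vox^2
}
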