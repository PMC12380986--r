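# Independent brute-force oracles, deliberately built on different machinery
# than the package's compiled implementations.

# 8-connected component labelling via igraph on an explicit adjacency graph
oracle_patches <- function(window, cls, valid = NULL, cell_size = 30) {
  if (is.null(valid)) valid <- matrix(TRUE, nrow(window), ncol(window))
  nr <- nrow(window); nc <- ncol(window)
  is_cls <- window == cls & valid
  cells <- which(is_cls)
  if (length(cells) == 0)
    return(data.frame(cells = integer(), perimeter = integer(),
                      area_ha = numeric()))
  rc <- arrayInd(cells, dim(window))
  id_of <- matrix(0L, nr, nc)
  id_of[cells] <- seq_along(cells)
  edges <- NULL
  for (k in seq_along(cells)) {
    r <- rc[k, 1]; c <- rc[k, 2]
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- r + dr; cc <- c + dc
      if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc && is_cls[rr, cc])
        edges <- rbind(edges, c(k, id_of[rr, cc]))
    }
  }
  g <- igraph::graph_from_edgelist(
    rbind(cbind(seq_along(cells), seq_along(cells)), edges),
    directed = FALSE)
  comp <- igraph::components(g)$membership[seq_along(cells)]
  out <- data.frame(comp = sort(unique(comp)))
  out$cells <- as.vector(table(comp))
  # perimeter: 4-neighbour exposures
  per <- numeric(nrow(out))
  for (k in seq_along(cells)) {
    r <- rc[k, 1]; c <- rc[k, 2]
    p <- 0
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      rr <- r + d[1]; cc <- c + d[2]
      if (rr < 1 || rr > nr || cc < 1 || cc > nc || !is_cls[rr, cc]) p <- p + 1
    }
    per[comp[k]] <- per[comp[k]] + p
  }
  out$perimeter <- per
  out$area_ha <- out$cells * cell_size^2 / 1e4
  out
}

# minimum polyomino perimeter by exhaustive enumeration of fixed polyominoes
oracle_min_perimeter <- function(n) {
  stopifnot(n >= 1, n <= 7)
  canon <- function(cells) {
    cells[, 1] <- cells[, 1] - min(cells[, 1])
    cells[, 2] <- cells[, 2] - min(cells[, 2])
    paste(sort(paste(cells[, 1], cells[, 2])), collapse = ";")
  }
  shapes <- list(matrix(c(0, 0), 1, 2))
  names(shapes) <- canon(shapes[[1]])
  for (size in seq_len(n - 1)) {
    grown <- list()
    for (s in shapes) {
      for (k in seq_len(nrow(s))) {
        for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
          cand <- c(s[k, 1] + d[1], s[k, 2] + d[2])
          if (!any(s[, 1] == cand[1] & s[, 2] == cand[2])) {
            s2 <- rbind(s, cand)
            grown[[canon(s2)]] <- s2
          }
        }
      }
    }
    shapes <- grown
  }
  perim <- function(s) {
    p <- 0
    for (k in seq_len(nrow(s))) {
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        cand <- c(s[k, 1] + d[1], s[k, 2] + d[2])
        if (!any(s[, 1] == cand[1] & s[, 2] == cand[2])) p <- p + 1
      }
    }
    p
  }
  min(vapply(shapes, perim, 0))
}

# direct formula evaluation of the six metrics from an oracle patch table
oracle_metrics <- function(window, cls, valid = NULL, cell_size = 30) {
  if (is.null(valid)) valid <- matrix(TRUE, nrow(window), ncol(window))
  Z <- sum(valid)
  p <- oracle_patches(window, cls, valid, cell_size)
  if (nrow(p) == 0) return(setNames(rep(NA_real_, 6),
                                    c("PA", "LPI", "COHESION", "LSI",
                                      "AREA_CV", "SHAPE")))
  minper <- function(n) vapply(n, function(ni) {
    m <- floor(sqrt(ni) + 1e-12)
    if (m * m == ni) 4 * m else if (ni <= m * (m + 1)) 4 * m + 2 else 4 * m + 4
  }, 0)
  mu <- mean(p$area_ha)
  c(PA = mean(p$area_ha),
    LPI = 100 * max(p$cells) / Z,
    COHESION = 100 * (1 - sum(p$perimeter) / sum(p$perimeter * sqrt(p$cells))) /
      (1 - 1 / sqrt(Z)),
    LSI = sum(p$perimeter) / minper(sum(p$cells)),
    AREA_CV = 100 * sqrt(mean((p$area_ha - mu)^2)) / mu,
    SHAPE = mean(p$perimeter / minper(p$cells)))
}

# exhaustive ROC threshold / AUC by looping over all candidate cutoffs
oracle_roc <- function(prob, labels) {
  cuts <- sort(unique(prob), decreasing = TRUE)
  np <- sum(labels == 1); nn <- sum(labels == 0)
  best_j <- -Inf; best_c <- NA
  for (cc in cuts) {
    tpr <- sum(prob >= cc & labels == 1) / np
    fpr <- sum(prob >= cc & labels == 0) / nn
    j <- tpr - fpr
    if (j > best_j + 1e-12) { best_j <- j; best_c <- cc }
  }
  conc <- 0
  for (i in which(labels == 1)) for (k in which(labels == 0))
    conc <- conc + (prob[i] > prob[k]) + 0.5 * (prob[i] == prob[k])
  list(threshold = best_c, auc = conc / (np * nn))
}

# small synthetic reflectance image with blocky structure plus noise
synthetic_reflectance <- function(n = 64, seed = 1, noise = 60) {
  set.seed(seed)
  base <- matrix(0, n, n)
  for (b in 1:4) {
    r <- sample(n, 2); c <- sample(n, 2)
    base[min(r):max(r), min(c):max(c)] <- base[min(r):max(r), min(c):max(c)] +
      runif(1, 300, 1500)
  }
  list(red = base * 0.2 + matrix(rnorm(n * n, sd = noise), n, n) + 300,
       nir = 3000 - base * 0.5 + matrix(rnorm(n * n, sd = noise), n, n),
       swir = base + matrix(rnorm(n * n, sd = noise), n, n) + 1000)
}
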