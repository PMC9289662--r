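# Community structure of the bipartite exposure network: Barber bipartite
# modularity, leading-eigenvector spectral bisection (with Newman-style
# single-node fine-tuning), and mutual information between partitions with a
# permutation null.

.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Bipartite partition container
#'
#' @param c_tract,c_park integer community ids (0-based, contiguous) per tract
#'   and park; `NA` for unassigned (zero-strength) nodes.
#' @param Q modularity of the partition (optional; computed by
#'   [bipartite_modularity()]).
#' @return object of class `bipartite_partition`.
#' @export
bipartite_partition <- function(c_tract, c_park, Q = NA_real_) {
  ids <- c(c_tract, c_park)
  ids <- ids[!is.na(ids)]
  k <- length(unique(ids))
  if (k > 0L && !setequal(unique(ids), 0:(k - 1L))) {
    stop("community ids must be contiguous 0..k-1")
  }
  structure(list(c_tract = c_tract, c_park = c_park, k = k, Q = Q),
            class = "bipartite_partition")
}

#' @export
print.bipartite_partition <- function(x, ...) {
  cat(sprintf("<bipartite_partition: %d communities, Q = %.4f>\n", x$k, x$Q))
  invisible(x)
}

#' Barber bipartite modularity
#'
#' `Q = (1/m) sum_ij (X_ij - s^T_i s^P_j / m) delta(c^T_i, c^P_j)`, comparing
#' observed link weights to the configuration-null expectation. Zero for the
#' all-in-one-community partition; at most 1.
#'
#' @param net an [exposure_network()] with total weight m > 0.
#' @param partition a [bipartite_partition()] (or a list with `c_tract`,
#'   `c_park`).
#' @return modularity Q.
#' @export
bipartite_modularity <- function(net, partition) {
  stopifnot(inherits(net, "exposure_network"))
  ct <- partition$c_tract; cp <- partition$c_park
  stopifnot(length(ct) == nrow(net$X), length(cp) == ncol(net$X))
  m <- sum(net$X)
  if (m <= 0) stop("modularity undefined for an empty network (m = 0)")
  Xt <- methods::as(net$X, "TsparseMatrix")
  i <- Xt@i + 1L; j <- Xt@j + 1L; w <- Xt@x
  same <- !is.na(ct[i]) & !is.na(cp[j]) & ct[i] == cp[j]
  obs <- sum(w[same])
  sT <- Matrix::rowSums(net$X); sP <- Matrix::colSums(net$X)
  comms <- unique(c(ct[!is.na(ct)], cp[!is.na(cp)]))
  exp_term <- 0
  for (cc in comms) {
    exp_term <- exp_term + sum(sT[which(ct == cc)]) * sum(sP[which(cp == cc)])
  }
  obs / m - exp_term / m^2
}

# f(s) = sum_ij B_ij s_i s_j for a +-1 split of one community;
# delta-Q of accepting the split is (f(s) - f(1)) / (2m)
.split_objective <- function(B, sT, sP) {
  as.numeric(t(sT) %*% B %*% sP)
}

# Kernighan-Lin fine-tuning of a +-1 split (Newman's fine-tuning stage):
# each pass flips every node exactly once, greedily by current gain (gains
# may be negative mid-pass), then reverts to the best intermediate state;
# passes repeat while the objective improves.
.fine_tune_split <- function(B, sT, sP, max_iter = 200L) {
  nT <- length(sT); nP <- length(sP)
  n <- nT + nP
  obj <- function(sT, sP) as.numeric(t(sT) %*% B %*% sP)
  for (pass in seq_len(max_iter)) {
    start_obj <- obj(sT, sP)
    cT <- sT; cP <- sP
    flipped <- rep(FALSE, n)
    states <- vector("list", n)
    vals <- numeric(n)
    for (step in seq_len(n)) {
      gT <- -2 * cT * as.numeric(B %*% cP)
      gP <- -2 * cP * as.numeric(crossprod(B, cT))
      g <- c(gT, gP)
      g[flipped] <- -Inf
      best <- which.max(g)
      if (best <= nT) cT[best] <- -cT[best] else cP[best - nT] <- -cP[best - nT]
      flipped[best] <- TRUE
      states[[step]] <- list(sT = cT, sP = cP)
      vals[step] <- obj(cT, cP)
    }
    best_step <- which.max(vals)
    if (vals[best_step] > start_obj + 1e-12) {
      sT <- states[[best_step]]$sT
      sP <- states[[best_step]]$sP
    } else {
      break
    }
  }
  list(sT = sT, sP = sP)
}

#' Detect communities by leading-eigenvector bisection
#'
#' Recursive spectral bisection applied directly to the bipartite modularity
#' matrix `B = X - s^T s^P' / m` over both node sets jointly: each candidate
#' split is the sign pattern of the leading eigenvector of the symmetric joint
#' matrix `[[0, B_g], [B_g', 0]]`, polished by a Kernighan-Lin pass, and
#' accepted only if it increases Q by more than `tol`. With `refine = TRUE`
#' (the default) the bisection-tree partition is then fine-tuned by multiway
#' Kernighan-Lin sweeps that move single nodes between communities (or into a
#' fresh one); on small networks (at most 64 connected nodes) a few
#' deterministic seeded random restarts guard against the rugged modularity
#' landscapes of sparse instances. Zero-strength nodes are left unassigned
#' (`NA`).
#'
#' @param net an [exposure_network()] with at least one link.
#' @param seed integer driving the deterministic restarts (the eigensolver is
#'   deterministic on its own).
#' @param tol minimal Q improvement for accepting a split (default 1e-10).
#' @param max_iter cap on fine-tuning iterations per split.
#' @param refine apply the multiway refinement stage (default TRUE).
#' @return a [bipartite_partition()] with `Q` equal to
#'   [bipartite_modularity()] of the returned partition.
#' @export
detect_communities <- function(net, seed = 1L, tol = 1e-10, max_iter = 200L,
                               refine = TRUE) {
  stopifnot(inherits(net, "exposure_network"))
  m <- sum(net$X)
  if (m <= 0) stop("network has no links")
  sT <- Matrix::rowSums(net$X); sP <- Matrix::colSums(net$X)
  conT <- which(sT > 0); conP <- which(sP > 0)
  if (length(conT) + length(conP) > 5000L) {
    stop("dense eigensolver limited to 5000 connected nodes")
  }
  B <- as.matrix(net$X[conT, conP, drop = FALSE]) - outer(sT[conT], sP[conP]) / m

  cT <- rep(0L, length(conT)); cP <- rep(0L, length(conP))
  next_id <- 1L
  queue <- list(list(iT = seq_along(conT), iP = seq_along(conP), id = 0L))
  while (length(queue) > 0L) {
    g <- queue[[1L]]; queue <- queue[-1L]
    nT <- length(g$iT); nP <- length(g$iP)
    if (nT + nP < 2L) next
    Bg <- B[g$iT, g$iP, drop = FALSE]
    M <- rbind(cbind(matrix(0, nT, nT), Bg),
               cbind(t(Bg), matrix(0, nP, nP)))
    ev <- eigen(M, symmetric = TRUE)
    if (ev$values[1L] <= tol) next
    v <- ev$vectors[, 1L]
    if (v[which.max(abs(v))] < 0) v <- -v
    s <- ifelse(v >= 0, 1, -1)
    ft <- .fine_tune_split(Bg, s[seq_len(nT)], s[nT + seq_len(nP)],
                           max_iter = max_iter)
    dQ <- (.split_objective(Bg, ft$sT, ft$sP) -
             .split_objective(Bg, rep(1, nT), rep(1, nP))) / (2 * m)
    neg <- c(ft$sT, ft$sP) < 0
    if (dQ <= tol || all(neg) || all(!neg)) next
    new_id <- next_id; next_id <- next_id + 1L
    cT[g$iT[ft$sT < 0]] <- new_id
    cP[g$iP[ft$sP < 0]] <- new_id
    queue <- c(queue,
               list(list(iT = g$iT[ft$sT > 0], iP = g$iP[ft$sP > 0], id = g$id),
                    list(iT = g$iT[ft$sT < 0], iP = g$iP[ft$sP < 0], id = new_id)))
  }
  if (refine) {
    n_con <- length(conT) + length(conP)
    if (n_con <= 256L) {
      sw <- .kl_multiway(B, cT, cP, m, tol = tol, max_pass = max_iter)
      cT <- sw$cT; cP <- sw$cP
      q_best <- .partition_Q(B, cT, cP, m)
      if (n_con <= 64L) {
        starts <- .with_seed(seed, {
          lapply(seq_len(10L), function(r) {
            list(cT = sample.int(4L, length(conT), replace = TRUE),
                 cP = sample.int(4L, length(conP), replace = TRUE))
          })
        })
        for (st in starts) {
          cand <- .kl_multiway(B, st$cT, st$cP, m, tol = tol, max_pass = max_iter)
          q_cand <- .partition_Q(B, cand$cT, cand$cP, m)
          if (q_cand > q_best + tol) {
            cT <- cand$cT; cP <- cand$cP; q_best <- q_cand
          }
        }
      }
    }
  }
  # contiguous ids in order of first appearance over (tracts, parks)
  ids <- unique(c(cT, cP))
  cT <- match(cT, ids) - 1L; cP <- match(cP, ids) - 1L
  c_tract <- rep(NA_integer_, nrow(net$X)); c_tract[conT] <- cT
  c_park <- rep(NA_integer_, ncol(net$X)); c_park[conP] <- cP
  part <- bipartite_partition(c_tract, c_park)
  part$Q <- bipartite_modularity(net, part)
  part$seed <- seed
  part
}

.partition_Q <- function(B, cT, cP, m) {
  sum(B * outer(cT, cP, "==")) / m
}

# Multiway Kernighan-Lin refinement: each pass force-moves every node exactly
# once to its best alternative community (an empty fresh community is always
# a candidate), allowing negative intermediate gains, then keeps the best
# intermediate state. Passes repeat while Q improves.
.kl_multiway <- function(B, cT, cP, m, tol = 1e-10, max_pass = 200L) {
  nT <- length(cT); nP <- length(cP); n <- nT + nP
  for (pass in seq_len(max_pass)) {
    q0 <- .partition_Q(B, cT, cP, m)
    bT <- cT; bP <- cP; bq <- q0
    wT <- cT; wP <- cP
    moved <- rep(FALSE, n)
    for (step in seq_len(n)) {
      comms <- sort(unique(c(wT, wP)))
      cand <- c(comms, max(comms) + 1L)
      bestg <- -Inf; bm <- NULL
      for (i in seq_len(nT)) {
        if (moved[i]) next
        S <- vapply(cand, function(cc) sum(B[i, which(wP == cc)]), 0)
        g <- (S - S[match(wT[i], cand)]) / m
        g[cand == wT[i]] <- -Inf
        w <- which.max(g)
        if (g[w] > bestg) { bestg <- g[w]; bm <- list(side = "T", idx = i, to = cand[w]) }
      }
      for (j in seq_len(nP)) {
        if (moved[nT + j]) next
        S <- vapply(cand, function(cc) sum(B[which(wT == cc), j]), 0)
        g <- (S - S[match(wP[j], cand)]) / m
        g[cand == wP[j]] <- -Inf
        w <- which.max(g)
        if (g[w] > bestg) { bestg <- g[w]; bm <- list(side = "P", idx = j, to = cand[w]) }
      }
      if (is.null(bm)) break
      if (bm$side == "T") { wT[bm$idx] <- bm$to; moved[bm$idx] <- TRUE }
      else { wP[bm$idx] <- bm$to; moved[nT + bm$idx] <- TRUE }
      q <- .partition_Q(B, wT, wP, m)
      if (q > bq + tol) { bq <- q; bT <- wT; bP <- wP }
    }
    if (bq > q0 + tol) { cT <- bT; cP <- bP } else break
  }
  list(cT = cT, cP = cP)
}

#' Shannon entropy of a labeling, in bits
#'
#' @param labels vector (NA dropped).
#' @return entropy in bits.
#' @export
entropy_bits <- function(labels) {
  labels <- labels[!is.na(labels)]
  if (length(labels) == 0L) return(0)
  p <- table(labels) / length(labels)
  -sum(ifelse(p > 0, p * log2(p), 0))
}

#' Mutual information between two labelings, in bits
#'
#' Plug-in (maximum-likelihood) estimator with log base 2:
#' `I = sum p(a,b) log2( p(a,b) / (p(a) p(b)) )`, with `0 log 0 = 0`.
#' Positions where either labeling is `NA` are excluded pairwise.
#'
#' @param labels_a,labels_b equal-length vectors.
#' @return mutual information in bits (>= 0).
#' @export
mutual_information <- function(labels_a, labels_b) {
  stopifnot(length(labels_a) == length(labels_b))
  ok <- !is.na(labels_a) & !is.na(labels_b)
  a <- labels_a[ok]; b <- labels_b[ok]
  n <- length(a)
  if (n == 0L) return(0)
  tab <- table(a, b) / n
  pa <- rowSums(tab); pb <- colSums(tab)
  ex <- outer(pa, pb)
  terms <- ifelse(tab > 0, tab * log2(tab / ex), 0)
  max(0, sum(terms))
}

#' Permutation null for mutual information
#'
#' Shuffles `labels_shuffled` uniformly `n` times while keeping
#' `labels_fixed` fixed, computing the plug-in mutual information for each
#' sample. Summarized as mean and sd (the "expected by chance" reference)
#' plus the one-sided exceedance fraction of the observed value.
#'
#' @param labels_fixed,labels_shuffled equal-length label vectors (NA excluded
#'   pairwise before shuffling).
#' @param n number of permutations (default 5000).
#' @param seed RNG seed (restores the caller's RNG state).
#' @param keep_samples keep the per-permutation MI samples.
#' @return object of class `mi_result`: `observed_bits`, `null_mean_bits`,
#'   `null_sd_bits`, `exceedance`, `n_permutations`, `seed` (and `samples`).
#' @export
permutation_null_mi <- function(labels_fixed, labels_shuffled, n = 5000L,
                                seed = NULL, keep_samples = FALSE) {
  if (n < 1L) stop("n must be >= 1")
  stopifnot(length(labels_fixed) == length(labels_shuffled))
  ok <- !is.na(labels_fixed) & !is.na(labels_shuffled)
  a <- labels_fixed[ok]; b <- labels_shuffled[ok]
  observed <- mutual_information(a, b)
  samples <- .with_seed(seed, {
    vapply(seq_len(n), function(k) mutual_information(a, sample(b)), 0)
  })
  structure(list(observed_bits = observed,
                 null_mean_bits = mean(samples),
                 null_sd_bits = if (n > 1L) stats::sd(samples) else 0,
                 exceedance = mean(samples >= observed),
                 n_permutations = as.integer(n),
                 seed = seed,
                 samples = if (keep_samples) samples else NULL),
            class = "mi_result")
}

#' @export
print.mi_result <- function(x, ...) {
  cat(sprintf("MI observed: %.4g bits; null: %.4g +- %.4g bits (%d permutations, exceedance %.4f)\n",
              x$observed_bits, x$null_mean_bits, x$null_sd_bits,
              x$n_permutations, x$exceedance))
  invisible(x)
}
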