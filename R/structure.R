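#' PCA on a genotype matrix
#'
#' Missing entries are mean-imputed per marker, markers are centered,
#' and scores come from the singular value decomposition of the
#' samples x markers matrix.  Markers with no called genotypes are
#' dropped with a message.
#'
#' @param g a `genotype_matrix`.
#' @param n_components number of components to return.
#' @return list of class `pca_result`: `scores` (n x c, rownames =
#'   sample ids), `explained_var` (fraction of total variance per
#'   component, non-increasing), `n_markers_used`.
#' @export
run_pca <- function(g, n_components = 10L) {
  gm <- unclass(g)
  if (nrow(gm) < 2 || ncol(gm) < 2) stop("PCA needs at least 2 markers and 2 samples")
  called <- rowSums(!is.na(gm))
  if (any(called == 0)) {
    message("run_pca: dropping ", sum(called == 0), " all-missing marker(s)")
    gm <- gm[called > 0, , drop = FALSE]
  }
  mu <- rowMeans(gm, na.rm = TRUE)
  X <- gm - mu                       # center per marker
  X[is.na(X)] <- 0                   # mean imputation
  X <- t(X)                          # samples x markers
  n_components <- min(n_components, nrow(X), ncol(X))
  sv <- svd(X, nu = n_components, nv = 0)
  total <- sum(sv$d^2)
  ev <- if (total > 0) sv$d^2 / total else rep(0, length(sv$d))
  scores <- sv$u %*% diag(sv$d[seq_len(n_components)], n_components)
  rownames(scores) <- colnames(g)
  colnames(scores) <- paste0("PC", seq_len(n_components))
  structure(list(scores = scores,
                 explained_var = ev[seq_len(n_components)],
                 n_markers_used = ncol(X)),
            class = "pca_result")
}

# Binomial admixture log-likelihood over called genotypes.
admixture_loglik <- function(W, M, P) {
  eps <- 1e-12
  P <- pmin(pmax(P, eps), 1 - eps)
  ll <- M * (W * log(P) + (2 - W) * log(1 - P) + log(ifelse(W == 1, 2, 1)))
  sum(ll)
}

#' Admixture estimation by EM under the binomial likelihood
#'
#' Maximizes
#' `sum over called (i,j) of log[ C(2, g_ij) pi^g (1 - pi)^(2 - g) ]`
#' with `pi_ij = sum_k Q_ik F_kj` over ancestry proportions Q (n x K)
#' and cluster allele frequencies F (K x m), by the classical EM updates
#' from a seeded random start.  Missing genotypes are skipped in the
#' likelihood.  The log-likelihood is non-decreasing at every iteration;
#' convergence is declared when the gain drops below `tol`.
#'
#' @param g a `genotype_matrix`.
#' @param K number of ancestry clusters (K <= n samples).
#' @param seed RNG seed for the start.
#' @param max_iter,tol EM iteration cap and log-likelihood tolerance.
#' @param init `"pca"` (default) seeds the clusters from k-means on the
#'   leading principal components, with cluster allele frequencies from
#'   the implied sample groups — this starts EM close to the dominant
#'   ancestry structure and cuts the iterations needed by an order of
#'   magnitude; `"random"` uses a Dirichlet/perturbed-frequency start.
#' @return list of class `admixture_model`: `Q`, `F_hat`, `loglik`
#'   (final value), `loglik_trace`, `K`, `n_iter`, `converged`.
#' @export
admixture_em <- function(g, K, seed = 1, max_iter = 500L, tol = 1e-4,
                         init = c("pca", "random")) {
  init <- match.arg(init)
  gm <- unclass(g)
  n <- ncol(gm); m <- nrow(gm)
  if (K < 1) stop("K must be >= 1")
  if (K > n) stop("K exceeds the number of samples")
  set.seed(seed)
  W <- t(gm)                          # n x m dosages
  M <- !is.na(W)                      # called mask
  W[!M] <- 0L
  M <- M * 1
  storage.mode(W) <- "double"

  phat <- colSums(W * M) / pmax(2 * colSums(M), 1)
  if (init == "pca" && K > 1) {
    pc <- suppressMessages(run_pca(g, n_components = max(K - 1, 2)))
    km <- suppressWarnings(
      stats::kmeans(pc$scores, centers = K, nstart = 5, iter.max = 50))
    Q <- matrix(0.05 / max(K - 1, 1), n, K)
    Q[cbind(seq_len(n), km$cluster)] <- 0.95
    F_hat <- matrix(NA_real_, K, m)
    for (k in seq_len(K)) {
      sel <- km$cluster == k
      Wk <- W[sel, , drop = FALSE]; Mk <- M[sel, , drop = FALSE]
      F_hat[k, ] <- colSums(Wk * Mk) / pmax(2 * colSums(Mk), 1)
      none <- colSums(Mk) == 0
      F_hat[k, none] <- phat[none]
    }
    F_hat <- pmin(pmax(F_hat, 0.02), 0.98)
  } else {
    # Dirichlet(1) rows for Q; observed frequency plus noise for F
    Q <- matrix(stats::rgamma(n * K, 1), n, K)
    Q <- Q / rowSums(Q)
    F_hat <- matrix(rep(phat, each = K), K, m) +
      matrix(stats::runif(K * m, -0.1, 0.1), K, m)
    F_hat <- pmin(pmax(F_hat, 0.02), 0.98)
  }

  eps <- 1e-9
  trace <- numeric(0)
  ll_old <- -Inf
  n_called <- rowSums(M)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    P <- Q %*% F_hat
    P <- pmin(pmax(P, eps), 1 - eps)
    ll <- admixture_loglik(W, M, P)
    trace <- c(trace, ll)
    if (is.finite(ll_old) && ll - ll_old < tol) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    Qnew <- matrix(0, n, K)
    A_sum <- matrix(0, K, m)
    AB_sum <- matrix(0, K, m)
    for (k in seq_len(K)) {
      QF <- outer(Q[, k], F_hat[k, ])
      QF1 <- outer(Q[, k], 1 - F_hat[k, ])
      A <- M * W * QF / P
      B <- M * (2 - W) * QF1 / (1 - P)
      Qnew[, k] <- rowSums(A) + rowSums(B)
      A_sum[k, ] <- colSums(A)
      AB_sum[k, ] <- colSums(A) + colSums(B)
    }
    Q <- Qnew / pmax(2 * n_called, 1)
    Q <- Q / rowSums(Q)               # guard against numeric drift
    F_hat <- A_sum / pmax(AB_sum, eps)
    F_hat <- pmin(pmax(F_hat, eps), 1 - eps)
  }
  rownames(Q) <- colnames(g)
  colnames(Q) <- paste0("K", seq_len(K))
  colnames(F_hat) <- rownames(g)
  structure(list(Q = Q, F_hat = F_hat, loglik = trace[length(trace)],
                 loglik_trace = trace, K = K, n_iter = it,
                 converged = converged),
            class = "admixture_model")
}

#' Markers genotyped in every population
#'
#' Returns the markers with at least `min_called` non-missing calls in
#' each population — the intersection set (in the bcftools-isec sense)
#' that structure analyses are run on.  Under depth-driven missingness
#' this subset is strongly enriched for well-covered sites, so its
#' per-entry missingness is far below the dataset average.
#'
#' @param g a `genotype_matrix`.
#' @param sheet a `sample_sheet` covering the samples of `g`.
#' @param min_called minimum calls per population (default 1).
#' @return character vector of marker ids.
#' @export
markers_called_in_all_pops <- function(g, sheet, min_called = 1L) {
  idx <- match(colnames(g), sheet$sample_id)
  if (anyNA(idx)) stop("samples absent from sheet")
  pops <- split(colnames(g), sheet$population[idx])
  ok <- rep(TRUE, nrow(g))
  for (p in pops) {
    ok <- ok & rowSums(!is.na(unclass(g)[, p, drop = FALSE])) >= min_called
  }
  rownames(g)[ok]
}

#' Choose K by masked-genotype cross-validation
#'
#' Called genotypes are partitioned into `folds` masking sets.  For each
#' K and each fold, the fold's genotypes are masked, the admixture model
#' is fitted on the remainder, and the fold error is the mean squared
#' difference between the masked dosages and their model expectation
#' `2 * pi_hat`.  The CV error is the average over folds and the best K
#' minimizes it.  With `folds = 1`, a single random `holdout_frac` of
#' called genotypes is masked instead.
#'
#' @param g a `genotype_matrix`.
#' @param k_range candidate K values.
#' @param seed RNG seed (masking and EM starts).
#' @param holdout_frac fraction of called genotypes masked when
#'   `folds = 1`.
#' @param folds number of cross-validation folds.
#' @param ... passed to [admixture_em()] (`max_iter`, `tol`).
#' @return list: `best_k`, `cv_table` (data.frame K, cv_error, loglik).
#' @export
select_k <- function(g, k_range, seed = 1, holdout_frac = 0.1, folds = 3L,
                     ...) {
  if (length(k_range) == 0) stop("k_range must be non-empty")
  gm <- unclass(g)
  called_idx <- which(!is.na(gm))
  set.seed(seed)
  ok_mask <- function(idx) {
    masked <- gm
    masked[idx] <- NA_integer_
    all(colSums(!is.na(masked)) > 0)
  }
  if (folds > 1L) {
    fold_of <- sample(rep(seq_len(folds), length.out = length(called_idx)))
    holds <- split(called_idx, fold_of)
  } else {
    draw_mask <- function() {
      sample(called_idx, size = max(1L, round(holdout_frac * length(called_idx))))
    }
    hold <- draw_mask()
    if (!ok_mask(hold)) {
      hold <- draw_mask()
      if (!ok_mask(hold)) stop("holdout masking emptied a sample; lower holdout_frac")
    }
    holds <- list(hold)
  }
  if (!all(vapply(holds, ok_mask, logical(1)))) {
    stop("masking emptied a sample; use more folds or fewer markers masked")
  }

  res <- lapply(seq_along(k_range), function(i) {
    K <- k_range[i]
    errs <- ll <- numeric(length(holds))
    for (h in seq_along(holds)) {
      hold <- holds[[h]]
      g_train <- gm
      g_train[hold] <- NA_integer_
      g_train <- genotype_matrix(g_train, rownames(gm), colnames(gm))
      fit <- admixture_em(g_train, K, seed = seed + i * 100L + h, ...)
      pred <- 2 * t(fit$Q %*% fit$F_hat)   # m x n expected dosage
      errs[h] <- mean((gm[hold] - pred[hold])^2)
      ll[h] <- fit$loglik
    }
    data.frame(K = K, cv_error = mean(errs), loglik = mean(ll))
  })
  cv_table <- do.call(rbind, res)
  list(best_k = cv_table$K[which.min(cv_table$cv_error)], cv_table = cv_table)
}

#' Assign samples to species from ancestry proportions
#'
#' A sample gets the label of its majority cluster when
#' `max_k Q_ik >= q_min`, and `"unassigned"` otherwise (hybrids and
#' ambiguous samples).  Replaces visual PCA-cluster assignment with a
#' reproducible rule; the cluster-to-species `labels` mapping must be
#' supplied (e.g. anchored on reference samples).
#'
#' @param model an `admixture_model`.
#' @param labels character vector of length K naming each cluster.
#' @param q_min assignment threshold on the majority ancestry fraction.
#' @return character vector of labels, named by sample id.
#' @export
assign_species <- function(model, labels, q_min = 0.8) {
  Q <- model$Q
  if (length(labels) != ncol(Q)) stop("labels must have one entry per cluster")
  top <- max.col(Q, ties.method = "first")
  out <- ifelse(Q[cbind(seq_len(nrow(Q)), top)] >= q_min,
                labels[top], "unassigned")
  stats::setNames(out, rownames(Q))
}

#' Match inferred clusters to true cluster labels
#'
#' Greedy alignment of the columns of an estimated Q matrix to those of
#' a truth Q matrix by maximal correlation; used to undo label switching
#' before comparing ancestry estimates.
#'
#' @param Q_hat,Q_true n x K ancestry matrices over the same samples.
#' @return integer permutation `perm` such that `Q_hat[, perm]` aligns
#'   with `Q_true`.
#' @export
align_clusters <- function(Q_hat, Q_true) {
  K <- ncol(Q_true)
  cc <- suppressWarnings(stats::cor(Q_hat, Q_true))
  cc[is.na(cc)] <- -Inf
  perm <- integer(K)
  used <- rep(FALSE, ncol(Q_hat))
  for (k in order(-apply(cc, 2, max))) {
    j <- order(-cc[, k])
    j <- j[!used[j]][1]
    perm[k] <- j
    used[j] <- TRUE
  }
  perm
}
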