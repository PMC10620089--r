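#' Cluster selectivity of a neuron
#'
#' `chi = |<z1> - <z2>| / (z_max - z_min)`, the normalised difference
#' between mean responses to the two clusters. A dead neuron
#' (`z_max == z_min`) has selectivity 0 by convention.
#'
#' @param mean_z1,mean_z2 Mean responses to the two clusters.
#' @param z_max,z_min Extreme responses across all probe inputs.
#' @return Selectivity in `[0, 1]`.
#' @export
cluster_selectivity <- function(mean_z1, mean_z2, z_max, z_min) {
  if (z_max < z_min) stop("'z_max' must be >= 'z_min'")
  if (z_max == z_min) return(0)
  min(abs(mean_z1 - mean_z2) / (z_max - z_min), 1)
}

#' Participation ratio of a representation
#'
#' `(sum lambda_i)^2 / sum lambda_i^2` over the eigenvalues of `Z' Z`.
#' Measures the effective dimensionality of the representation: 1 for
#' rank-one data, `N` for isotropic data. By default `Z` is mean-centred
#' first (so the eigenvalues are proportional to covariance eigenvalues);
#' `center = FALSE` uses `Z' Z` exactly as printed.
#'
#' @param reps B x N representation matrix, B >= 2.
#' @param center Mean-centre the columns first (default `TRUE`).
#' @return Participation ratio in `[1, min(B - 1, N)]` (centred case).
#' @export
participation_ratio <- function(reps, center = TRUE) {
  Z <- as.matrix(reps)
  if (nrow(Z) < 2) stop("need at least two samples")
  if (center) Z <- sweep(Z, 2, colMeans(Z))
  G <- crossprod(Z)
  lam <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  lam[lam < 0] <- 0
  s <- sum(lam)
  if (s <= 0) {
    warning("all-zero representation; participation ratio defined as 1")
    return(1)
  }
  s^2 / sum(lam^2)
}

#' Linear readout accuracy on frozen representations
#'
#' Fits an L2-regularised multinomial logistic regression (ridge) on the
#' training representations and reports held-out accuracy. The upstream
#' network stays frozen; only the readout is trained.
#'
#' @param train_reps,test_reps B x N representation matrices.
#' @param train_labels,test_labels Class labels.
#' @param lambda Ridge penalty (default 1e-3).
#' @return Accuracy in `[0, 1]`.
#' @export
linear_readout_accuracy <- function(train_reps, train_labels,
                                    test_reps, test_labels, lambda = 1e-3) {
  train_labels <- factor(train_labels)
  if (nlevels(train_labels) < 2) stop("need at least two classes")
  test_labels <- factor(test_labels, levels = levels(train_labels))
  train_reps <- as.matrix(train_reps); test_reps <- as.matrix(test_reps)
  if (ncol(train_reps) < 2) { # glmnet requires >= 2 predictors
    train_reps <- cbind(train_reps, 0)
    test_reps <- cbind(test_reps, 0)
  }
  fit <- glmnet::glmnet(as.matrix(train_reps), train_labels,
                        family = "multinomial", alpha = 0, lambda = lambda,
                        standardize = FALSE)
  pred <- predict(fit, as.matrix(test_reps), type = "class")
  mean(pred == as.character(test_labels))
}

#' Signal selectivity from afferent weights
#'
#' `chi = (w_P - w_Pctl) / (w_P + w_Pctl)`: the relative difference between
#' a neuron's mean afferent weight from a slow-signal pathway and from its
#' shuffled control pathway. Positive values mean the slow signal is
#' preferred.
#'
#' @param w_signal,w_control Nonnegative mean afferent weights (vectors are
#'   processed elementwise).
#' @return Values in `[-1, 1]`; 0 with a warning where both weights are 0.
#' @export
signal_selectivity <- function(w_signal, w_control) {
  if (any(w_signal < 0) || any(w_control < 0))
    stop("mean weights must be nonnegative")
  tot <- w_signal + w_control
  out <- ifelse(tot == 0, 0, (w_signal - w_control) / tot)
  if (any(tot == 0)) warning("both weights zero; selectivity set to 0")
  out
}

#' Relative tuning between the two slow-signal pathways
#'
#' `chi_rel = (w_P2 - w_P1) / (w_P2 + w_P1)`.
#'
#' @param w_p2,w_p1 Nonnegative mean afferent weights.
#' @return Values in `[-1, 1]`; 0 with a warning where both weights are 0.
#' @export
relative_tuning <- function(w_p2, w_p1) {
  if (any(w_p2 < 0) || any(w_p1 < 0)) stop("mean weights must be nonnegative")
  tot <- w_p2 + w_p1
  out <- ifelse(tot == 0, 0, (w_p2 - w_p1) / tot)
  if (any(tot == 0)) warning("both weights zero; tuning set to 0")
  out
}

#' Reconstruct target rate traces from binned network activity
#'
#' L1-regularised (Lasso) linear regression from binned network firing rates
#' to each target trace; the model is fit on the leading portion of the data
#' and R-squared is reported on the held-out tail.
#'
#' @param network_rates Bins x neurons matrix of network rates (e.g. from
#'   [bin_raster()]).
#' @param target_traces Bins x targets matrix (or vector) of rate traces on
#'   the same bin grid.
#' @param train_frac Fraction of bins used for fitting (default 0.95,
#'   i.e. the last 5% are held out).
#' @param lambda Lasso penalty; `NULL` (default) selects it by glmnet's
#'   internal path at the value minimising training deviance among a small
#'   fixed path.
#' @return Numeric vector of held-out R-squared values, one per target.
#' @export
reconstruct_inputs <- function(network_rates, target_traces,
                               train_frac = 0.95, lambda = 0.01) {
  X <- as.matrix(network_rates)
  Y <- as.matrix(target_traces)
  if (nrow(X) != nrow(Y)) stop("bins misaligned between activity and targets")
  n <- nrow(X)
  n_train <- floor(train_frac * n)
  if (n_train < 2 || n_train >= n) stop("train/test split degenerate")
  tr <- seq_len(n_train); te <- (n_train + 1L):n
  vapply(seq_len(ncol(Y)), function(j) {
    fit <- glmnet::glmnet(X[tr, , drop = FALSE], Y[tr, j], alpha = 1,
                          lambda = lambda)
    pred <- as.numeric(predict(fit, X[te, , drop = FALSE]))
    ss_res <- sum((Y[te, j] - pred)^2)
    ss_tot <- sum((Y[te, j] - mean(Y[te, j]))^2)
    if (ss_tot == 0) return(NA_real_)
    1 - ss_res / ss_tot
  }, numeric(1))
}

#' Averaged representational similarity matrix for one factor
#'
#' Cosine similarity between mean representations at each level of `factor`,
#' computed within every combination of the remaining factors and averaged.
#'
#' @param reps B x N representation matrix.
#' @param labels Data frame of factor level assignments (one row per
#'   representation).
#' @param factor Name of the factor whose levels index the RSM.
#' @param marginalize Names of the remaining factors to average over
#'   (default: all other columns of `labels`).
#' @return A levels x levels similarity matrix.
#' @export
representational_similarity <- function(reps, labels, factor,
                                        marginalize = setdiff(colnames(labels),
                                                              factor)) {
  Z <- as.matrix(reps)
  lev <- sort(unique(labels[[factor]]))
  ctx <- if (length(marginalize))
    interaction(labels[marginalize], drop = TRUE) else factor(rep(1, nrow(Z)))
  acc <- matrix(0, length(lev), length(lev))
  cnt <- matrix(0, length(lev), length(lev))
  for (g in levels(ctx)) {
    sel <- ctx == g
    means <- lapply(lev, function(v) {
      rows <- sel & labels[[factor]] == v
      if (!any(rows)) return(NULL)
      colMeans(Z[rows, , drop = FALSE])
    })
    for (i in seq_along(lev)) for (j in seq_along(lev)) {
      mi <- means[[i]]; mj <- means[[j]]
      if (is.null(mi) || is.null(mj)) next
      ni <- sqrt(sum(mi^2)); nj <- sqrt(sum(mj^2))
      if (ni == 0 || nj == 0) next
      acc[i, j] <- acc[i, j] + sum(mi * mj) / (ni * nj)
      cnt[i, j] <- cnt[i, j] + 1
    }
  }
  if (any(cnt == 0)) stop("empty factor cell")
  out <- acc / cnt
  dimnames(out) <- list(lev, lev)
  out
}

#' Disentanglement score (majority-vote metric)
#'
#' For each factor, find the unit that is most insensitive to all other
#' factors (smallest variance of its normalised response when the chosen
#' factor is held fixed), then train a majority-vote classifier that maps
#' the index of the least-variable unit of a sample batch to the identity of
#' the fixed factor; report its accuracy on held-out batches.
#'
#' @param reps B x N representation matrix.
#' @param labels Data frame of full factor annotations.
#' @param n_votes Number of voting batches (default 200).
#' @param batch Samples per voting batch (default 32).
#' @param train_frac Fraction of votes used to build the vote table.
#' @param seed Integer seed for batch resampling.
#' @return Score in `[0, 1]` (chance is `1 / n_factors`).
#' @export
disentanglement_score <- function(reps, labels, n_votes = 200L, batch = 32L,
                                  train_frac = 0.5, seed = 1L) {
  Z <- as.matrix(reps)
  keep <- vapply(labels, function(col) length(unique(col)) > 1, logical(1))
  if (!all(keep)) warning("excluding single-level factor(s): ",
                          paste(names(labels)[!keep], collapse = ", "))
  labels <- labels[keep]
  fac_names <- colnames(labels)
  if (length(fac_names) < 2) stop("need at least two multi-level factors")
  sdz <- apply(Z, 2, sd); sdz[sdz == 0] <- 1
  Zn <- sweep(Z, 2, sdz, "/")
  set.seed(seed)
  votes <- data.frame(factor = integer(n_votes), unit = integer(n_votes))
  for (v in seq_len(n_votes)) {
    fi <- sample.int(length(fac_names), 1L)
    lv <- sample(unique(labels[[fi]]), 1L)
    rows <- which(labels[[fi]] == lv)
    rows <- rows[sample.int(length(rows), min(batch, length(rows)),
                            replace = length(rows) < batch)]
    vars <- apply(Zn[rows, , drop = FALSE], 2, var)
    votes$factor[v] <- fi
    votes$unit[v] <- which.min(vars)
  }
  n_train <- floor(train_frac * n_votes)
  tr <- votes[seq_len(n_train), ]; te <- votes[(n_train + 1L):n_votes, ]
  vote_table <- tapply(tr$factor, tr$unit, function(f)
    as.integer(names(which.max(table(f)))))
  pred <- vote_table[as.character(te$unit)]
  fallback <- as.integer(names(which.max(table(tr$factor))))
  pred[is.na(pred)] <- fallback
  mean(pred == te$factor)
}
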