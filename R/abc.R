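#' Rejection step: closest reference simulations to the observed data
#'
#' Euclidean distance on median/MAD-normalized statistics; the accepted set
#' is the `ceiling(tolerance * nrow)` closest rows, ties at the cutoff
#' broken by row order.
#'
#' @param observed named summary-statistic vector on the table's registry.
#' @param table a [build_reference_table()] object.
#' @param tolerance accepted fraction of the table, in (0, 1].
#' @return A list with `index` (accepted row indices), `distance`
#'   (distances of all rows) and `n_accepted`.
#' @export
rejection_sample <- function(observed, table, tolerance = 0.01) {
  stopifnot(inherits(table, "ref_table"),
            tolerance > 0, tolerance <= 1)
  check_registry(observed, table)
  zobs <- normalize_stats(table, observed)
  z <- if (is.null(table$znorm)) normalize_stats(table, table$stats) else
    table$znorm
  d2 <- rowSums(sweep(z, 2L, as.numeric(zobs))^2)
  dist <- sqrt(d2)
  n_acc <- as.integer(ceiling(tolerance * nrow(table$stats)))
  idx <- order(dist)[seq_len(n_acc)]  # order() is stable: ties by row order
  list(index = idx, distance = dist, n_accepted = n_acc)
}

check_registry <- function(observed, table) {
  nm <- colnames(table$stats)
  if (length(observed) != length(nm))
    stop("registry mismatch: observed vector has ", length(observed),
         " statistics, table expects ", length(nm))
  if (!is.null(names(observed)) && !identical(names(observed), nm))
    stop("registry mismatch: statistic names differ from the table's")
  invisible(TRUE)
}

epanechnikov <- function(dist) {
  dmax <- max(dist)
  if (dmax == 0) return(rep(1, length(dist)))
  1 - (dist / dmax)^2
}

#' ABC scenario choice
#'
#' Posterior scenario probabilities from the accepted rows, either as plain
#' rejection proportions or (default) via the logistic-regression estimator:
#' a multinomial logit of the scenario indicator on the normalized
#' statistics (centered at the observed vector) with Epanechnikov distance
#' weights, evaluated at the observed data. A direct-rejection estimate is
#' always reported alongside. 95% intervals come from the fit's parameter
#' covariance by the delta method. On complete separation or a failed fit
#' the method falls back to rejection proportions with a warning.
#'
#' @param observed named summary-statistic vector.
#' @param table a [build_reference_table()] object.
#' @param tolerance accepted fraction for the rejection step.
#' @param method `"logistic"` (default) or `"rejection"`.
#' @param ci compute 95% intervals (requires the logit Hessian; disable for
#'   bulk classification).
#' @return An object of class `abc_model_choice`.
#' @export
model_choice <- function(observed, table, tolerance = 0.01,
                         method = c("logistic", "rejection"), ci = TRUE) {
  method <- match.arg(method)
  rej <- rejection_sample(observed, table, tolerance)
  scen <- table$scenario[rej$index]
  labels <- sort(unique(table$scenario))
  counts <- setNames(tabulate(factor(scen, levels = labels),
                              nbins = length(labels)), labels)
  rej_post <- counts / sum(counts)
  w <- epanechnikov(rej$distance[rej$index])
  post <- rej_post
  ci_m <- NULL
  used <- "rejection"
  if (method == "logistic" && length(unique(scen)) >= 2L) {
    zfull <- if (is.null(table$znorm)) normalize_stats(table, table$stats)
      else table$znorm
    z <- zfull[rej$index, , drop = FALSE]
    zobs <- as.numeric(normalize_stats(table, observed))
    X <- sweep(z, 2L, zobs)
    fit <- try(suppressWarnings(
      nnet::multinom(y ~ ., data = data.frame(y = factor(scen,
                                                         levels = labels[labels %in% scen]),
                                              X, check.names = FALSE),
                     weights = w, trace = FALSE, maxit = 300L,
                     Hess = ci, MaxNWts = 5000L)), silent = TRUE)
    ok <- !inherits(fit, "try-error")
    if (ok) {
      cf <- coef(fit)
      ok <- all(is.finite(cf)) && max(abs(cf)) < 50
    }
    if (ok) {
      present <- labels[labels %in% scen]
      newd <- as.data.frame(matrix(0, 1L, ncol(X)))
      colnames(newd) <- colnames(X)
      p <- predict(fit, newdata = newd, type = "probs")
      if (length(present) == 2L) p <- c(1 - p, p)
      p <- setNames(as.numeric(p), present)
      post[] <- 0
      post[present] <- p
      used <- "logistic"
      if (ci) ci_m <- logistic_ci(fit, post, present, labels)
    } else {
      warning("logistic fit failed or separated; falling back to ",
              "rejection proportions")
    }
  } else if (method == "logistic") {
    used <- "logistic"  # degenerate: single scenario accepted
  }
  if (is.null(ci_m)) {
    ci_m <- cbind(lower = pmax(post, 0), upper = pmin(post, 1))
    rownames(ci_m) <- labels
  }
  structure(list(posterior = post, ci = ci_m,
                 rejection_posterior = rej_post, counts = counts,
                 tolerance = tolerance, method = used,
                 n_accepted = rej$n_accepted),
            class = "abc_model_choice")
}

# delta-method 95% intervals for softmax(intercepts) of a multinom fit
logistic_ci <- function(fit, post, present, labels) {
  ci_m <- cbind(lower = pmax(post, 0), upper = pmin(post, 1))
  rownames(ci_m) <- names(post)
  V <- try(suppressWarnings(stats::vcov(fit)), silent = TRUE)
  if (inherits(V, "try-error")) return(ci_m)
  pn <- rownames(V)
  ipos <- grep("(Intercept)", pn, fixed = TRUE)
  if (length(ipos) == 0L) return(ci_m)
  Vi <- V[ipos, ipos, drop = FALSE]
  p <- post[present]
  K <- length(present)
  for (j in seq_len(K)) {
    # gradient of p_j wrt the K-1 free intercepts (classes 2..K)
    g <- vapply(2:K, function(m) p[[j]] * ((j == m) - p[[m]]), 0)
    v <- drop(t(g) %*% Vi %*% g)
    half <- 1.959964 * sqrt(max(v, 0))
    ci_m[present[[j]], ] <- c(max(p[[j]] - half, 0), min(p[[j]] + half, 1))
  }
  ci_m
}

#' @export
print.abc_model_choice <- function(x, ...) {
  cat("<abc_model_choice> method = ", x$method, ", tolerance = ",
      x$tolerance, " (", x$n_accepted, " accepted)\n", sep = "")
  df <- data.frame(posterior = round(x$posterior, 4L),
                   lower95 = round(x$ci[, "lower"], 4L),
                   upper95 = round(x$ci[, "upper"], 4L),
                   rejection = round(x$rejection_posterior, 4L),
                   accepted = x$counts)
  print(df)
  invisible(x)
}

#' ABC parameter posteriors (local-linear adjustment)
#'
#' Restricts the table to one scenario, performs the rejection step there,
#' and applies the local-linear regression adjustment: each (log-scale)
#' parameter is regressed on the normalized statistics centered at the
#' observed vector with Epanechnikov weights, and the accepted draws are
#' shifted to the observed point. Weighted 2.5/50/97.5% quantiles of the
#' adjusted sample are reported, back-transformed to natural units. A
#' singular design falls back to a small ridge penalty with a warning.
#'
#' @param observed named summary-statistic vector.
#' @param table a [build_reference_table()] object.
#' @param scenario scenario label to condition on (e.g. `"S2"`).
#' @param tolerance accepted fraction of the scenario's rows.
#' @param log_transform adjust strictly positive parameters on the log
#'   scale (default; parameters with non-positive draws are adjusted
#'   untransformed).
#' @return An object of class `abc_posterior` with the adjusted sample,
#'   weights and a summary table (median and 95% interval per parameter).
#' @export
estimate_parameters <- function(observed, table, scenario,
                                tolerance = 0.01, log_transform = TRUE) {
  stopifnot(inherits(table, "ref_table"))
  rows <- which(table$scenario == scenario)
  if (length(rows) == 0L) stop("scenario ", scenario, " not in table")
  sub <- table
  sub$scenario <- table$scenario[rows]
  sub$stats <- table$stats[rows, , drop = FALSE]
  sub$params <- table$params[rows, , drop = FALSE]
  if (!is.null(sub$znorm))
    sub$znorm <- sub$znorm[rows, , drop = FALSE]
  rej <- rejection_sample(observed, sub, tolerance)
  idx <- rej$index
  w <- epanechnikov(rej$distance[idx])
  params <- sub$params[idx, , drop = FALSE]
  params <- rename_time_params(params, table, scenario)
  adjusted <- params
  if (length(idx) >= 3L) {
    z <- normalize_stats(table, sub$stats)[idx, , drop = FALSE]
    zobs <- as.numeric(normalize_stats(table, observed))
    X <- sweep(z, 2L, zobs)
    for (j in seq_len(ncol(params))) {
      y <- params[, j]
      uselog <- log_transform && all(y > 0)
      ty <- if (uselog) log(y) else y
      beta <- local_linear_beta(X, ty, w)
      adj <- ty - drop(X %*% beta)
      adjusted[, j] <- if (uselog) exp(adj) else adj
    }
  }
  qs <- t(apply(adjusted, 2L, weighted_quantile, w = w,
                probs = c(0.025, 0.5, 0.975)))
  summary <- data.frame(parameter = colnames(adjusted),
                        median = qs[, 2L], lower95 = qs[, 1L],
                        upper95 = qs[, 3L], row.names = NULL,
                        stringsAsFactors = FALSE)
  structure(list(scenario = scenario, tolerance = tolerance,
                 n_accepted = length(idx), adjusted = adjusted,
                 weights = w, summary = summary),
            class = "abc_posterior")
}

# weighted least squares slope vector; ridge fallback on singular designs
local_linear_beta <- function(X, y, w) {
  Xd <- cbind(1, X)
  fit <- try(stats::lm.wfit(Xd, y, w), silent = TRUE)
  if (!inherits(fit, "try-error") && fit$rank == ncol(Xd))
    return(fit$coefficients[-1L])
  warning("singular local-linear design; using ridge fallback")
  WX <- Xd * w
  A <- crossprod(WX, Xd) + diag(1e-6, ncol(Xd))
  drop(solve(A, crossprod(WX, y)))[-1L]
}

rename_time_params <- function(params, table, scenario) {
  tn <- table$time_names[[scenario]]
  cn <- colnames(params)
  if (!is.null(tn)) {
    cn[cn == "t1_yr"] <- tn[[1L]]
    cn[cn == "t2_yr"] <- tn[[2L]]
  }
  colnames(params) <- cn
  params
}

weighted_quantile <- function(x, w, probs) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  vapply(probs, function(p) x[[which(cw >= p)[[1L]]]], 0)
}

#' @export
print.abc_posterior <- function(x, ...) {
  cat("<abc_posterior> scenario ", x$scenario, ", ", x$n_accepted,
      " accepted draws (tolerance ", x$tolerance, ")\n", sep = "")
  print(x$summary, digits = 4L)
  invisible(x)
}

#' Confidence in scenario choice via pseudo-observed datasets
#'
#' Simulates `n_pods_per_scenario` pseudo-observed datasets (PODs) from each
#' scenario's priors, classifies each by the highest logistic-regression
#' posterior against the reference table (ties broken toward the lower
#' scenario index), and reports per-scenario type I error (true-scenario
#' PODs assigned elsewhere) and type II error (other-scenario PODs assigned
#' to it).
#'
#' @param scenarios list of [build_scenario()] objects or labels; must match
#'   the table's scenarios.
#' @param priors prior set used to draw the POD parameters.
#' @param table a [build_reference_table()] object.
#' @param n_pods_per_scenario PODs per scenario.
#' @param tolerance accepted fraction for each classification.
#' @param design sampling design of the PODs (defaults to the table's).
#' @param gen_time generation time in years.
#' @return An object of class `abc_confusion` with the assignment matrix
#'   and per-scenario error rates.
#' @export
evaluate_confidence <- function(scenarios, priors = default_priors(), table,
                                n_pods_per_scenario = 100L,
                                tolerance = 0.01, design = NULL,
                                gen_time = 2) {
  scenarios <- lapply(scenarios, function(s)
    if (inherits(s, "demographic_scenario")) s else build_scenario(s))
  if (is.null(design)) design <- table$design
  labels <- vapply(scenarios, `[[`, "", "label")
  tab_labels <- sort(unique(table$scenario))
  if (!setequal(labels, tab_labels))
    stop("scenario labels do not match the reference table")
  assigned <- matrix(0L, length(labels), length(labels),
                     dimnames = list(true = labels, assigned = tab_labels))
  for (si in seq_along(scenarios)) {
    sc <- scenarios[[si]]
    for (r in seq_len(n_pods_per_scenario)) {
      dr <- draw_parameters(priors, sc, gen_time = gen_time)
      ds <- simulate_dataset(sc, dr, design)
      ss <- assemble_sumstats(ds$aln, ds$ms, ds$map, table$registry)
      mc <- suppressWarnings(
        model_choice(ss, table, tolerance, ci = FALSE))
      best <- tab_labels[[which.max(mc$posterior)]]  # which.max: lowest index wins ties
      assigned[sc$label, best] <- assigned[sc$label, best] + 1L
    }
  }
  n <- rowSums(assigned)
  type1 <- 1 - diag(assigned) / n
  type2 <- vapply(seq_along(labels), function(j)
    sum(assigned[-j, j]) / sum(n[-j]), 0)
  names(type2) <- colnames(assigned)
  structure(list(assigned = assigned, type1 = type1, type2 = type2,
                 n_pods_per_scenario = n_pods_per_scenario,
                 tolerance = tolerance),
            class = "abc_confusion")
}

#' @export
print.abc_confusion <- function(x, ...) {
  cat("<abc_confusion> ", x$n_pods_per_scenario,
      " pseudo-observed datasets per scenario\n", sep = "")
  print(x$assigned)
  cat("type I error: ", paste(sprintf("%s=%.3f", names(x$type1), x$type1),
                              collapse = ", "), "\n", sep = "")
  cat("type II error:", paste(sprintf("%s=%.3f", names(x$type2), x$type2),
                              collapse = ", "), "\n")
  invisible(x)
}

#' Prior-predictive check of the observed statistics
#'
#' For each statistic and each scenario, the quantile of the observed value
#' within that scenario's simulated distribution; statistics falling outside
#' \[0.025, 0.975\] are flagged as poorly fit by the scenario.
#'
#' @param observed named summary-statistic vector.
#' @param table a [build_reference_table()] object.
#' @return A data.frame with one row per statistic x scenario: `statistic`,
#'   `scenario`, `quantile`, `flagged`.
#' @export
prior_predictive_check <- function(observed, table) {
  check_registry(observed, table)
  labels <- sort(unique(table$scenario))
  out <- do.call(rbind, lapply(labels, function(sc) {
    rows <- table$scenario == sc
    q <- vapply(seq_along(observed), function(j) {
      sim <- table$stats[rows, j]
      (sum(sim < observed[[j]]) + 0.5 * sum(sim == observed[[j]])) /
        length(sim)
    }, 0)
    data.frame(statistic = colnames(table$stats), scenario = sc,
               quantile = q, flagged = q < 0.025 | q > 0.975,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
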