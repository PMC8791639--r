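#' Split a sort-seq library into training/validation/evaluation sets
#'
#' Random partition by (unique) sequence, reproducible under the seed.
#'
#' @param lib a `sortseq_library`.
#' @param fractions three non-negative fractions summing to 1
#'   (default 60:20:20).
#' @param seed RNG seed.
#' @return named list of three disjoint `sortseq_library` objects
#'   (`training`, `validation`, `evaluation`).
#' @export
split_library <- function(lib, fractions = c(0.6, 0.2, 0.2), seed = 1L) {
  stopifnot(length(fractions) == 3, all(fractions >= 0),
            abs(sum(fractions) - 1) < 1e-8)
  n <- length(lib$sequences)
  if (n < ncol(lib$counts)) stop("fewer sequences than bins")
  sizes <- diff(c(0, floor(cumsum(fractions) * n)))
  idx <- with_fixed_seed(seed, sample.int(n))
  grp <- rep.int(1:3, sizes)
  out <- lapply(1:3, function(g) {
    sel <- sort(idx[grp == g])
    subset_library(lib, sel)
  })
  names(out) <- c("training", "validation", "evaluation")
  out
}

#' Fit the normalized per-bin logistic link
#'
#' Maximum-likelihood fit of the link between the model phenotype
#' x = log10 P_on and the observed expression bin: each bin i has
#' log(pi_i / (1 - pi_i)) = a_i x + b_i, and the probability of bin i is
#' P_i = pi_i / sum_j pi_j. The fit is balanced: unless explicit weights
#' are given, each record is weighted inversely to the number of
#' observations in its bin.
#'
#' @param x numeric vector of log10 P_on.
#' @param bins integer vector of observed bins (0-based or any integer
#'   labels; all bins 0..B-1 must be representable).
#' @param weights optional per-record weights; default balanced.
#' @param B number of bins (default `max(bins) + 1`).
#' @return a `logistic_link`: list with per-bin slopes `a`, intercepts
#'   `b`, the weighted `loglik`, and flags.
#' @export
fit_logistic <- function(x, bins, weights = NULL, B = NULL) {
  keep <- is.finite(x) & !is.na(bins)
  x <- x[keep]; bins <- as.integer(bins[keep])
  if (length(unique(bins)) < 2) stop("need at least 2 distinct bins")
  if (is.null(B)) B <- max(bins) + 1L
  if (is.null(weights)) weights <- balanced_weights(bins, B)
  else weights <- weights[keep]

  degenerate <- stats::sd(x) < 1e-12
  # optimize on the standardized phenotype (well-scaled curvature for
  # BFGS); coefficients are mapped back to the raw scale at the end
  x_center <- mean(x)
  x_scale <- if (degenerate) 1 else stats::sd(x)
  x <- (x - x_center) / x_scale
  lse_parts <- function(p, fit_a) {
    a <- if (fit_a) p[1:B] else rep(0, B)
    b <- p[(if (fit_a) B else 0) + 1:B]
    Z <- outer(x, a) + matrix(b, length(x), B, byrow = TRUE)
    lsig <- ifelse(Z > -35, -log1p(exp(-Z)), Z)  # log sigma, stable
    mx <- apply(lsig, 1, max)
    logS <- mx + log(rowSums(exp(lsig - mx)))
    list(a = a, lsig = lsig, logS = logS)
  }
  ll_fun <- function(p, fit_a = TRUE) {
    pp <- lse_parts(p, fit_a)
    iy <- cbind(seq_along(x), bins + 1L)
    sum(weights * (pp$lsig[iy] - pp$logS))
  }
  gr_fun <- function(p, fit_a = TRUE) {
    pp <- lse_parts(p, fit_a)
    S <- exp(pp$lsig)
    Y <- matrix(0, length(x), B); Y[cbind(seq_along(x), bins + 1L)] <- 1
    # d/dz_i of (log sig_y - log sum sig) = 1{y=i}(1-sig_i) - sig_i(1-sig_i)/S
    D <- (Y * (1 - S) - exp(pp$lsig - pp$logS) * (1 - S)) * weights
    gb <- colSums(D)
    if (fit_a) c(colSums(D * x), gb) else gb
  }
  if (degenerate) {
    p0 <- rep(0, B)
    opt <- stats::optim(p0, ll_fun, gr_fun, fit_a = FALSE, method = "BFGS",
                        control = list(fnscale = -1, maxit = 500))
    a <- rep(0, B); b <- opt$par
  } else {
    # initialize each bin's logistic from its own membership GLM (the
    # link's defining per-bin regressions); the joint solve then only
    # polishes the normalization
    a0 <- b0 <- numeric(B)
    for (i in seq_len(B) - 1L) {
      yy <- as.numeric(bins == i)
      if (sum(yy) == 0) { a0[i + 1] <- 0; b0[i + 1] <- -10; next }
      co <- tryCatch(suppressWarnings(
        stats::glm.fit(cbind(1, x), yy, weights = weights,
                       family = stats::binomial())$coefficients),
        error = function(e) c(0, 0))
      co[!is.finite(co)] <- 0
      b0[i + 1] <- max(min(co[1], 500), -500)
      a0[i + 1] <- max(min(co[2], 500), -500)
    }
    a0 <- pmax(pmin(a0, 100), -100)
    b0 <- pmax(pmin(b0, 100), -100)
    i0 <- seq_len(B) - 1L
    a1 <- (i0 - mean(i0)) / max(stats::sd(x), 0.1)
    starts <- list(c(a0, b0), c(a1, -a1 * mean(x)), rep(0, 2 * B))
    best <- NULL
    for (p0 in starts) {
      o <- stats::optim(p0, ll_fun, gr_fun, method = "BFGS",
                        control = list(fnscale = -1, maxit = 600))
      if (is.null(best) || o$value > best$value) best <- o
    }
    opt <- best
    a <- opt$par[1:B]; b <- opt$par[B + 1:B]
  }
  # map standardized-scale coefficients back to the raw phenotype scale
  b <- b - a * x_center / x_scale
  a <- a / x_scale
  structure(list(a = a, b = b, B = B, loglik = opt$value,
                 degenerate = degenerate,
                 converged = opt$convergence == 0),
            class = "logistic_link")
}

#' Balanced record weights
#'
#' Weights inversely proportional to the number of observations in each
#' bin, normalized to mean 1.
#' @param bins integer bin labels (0-based).
#' @param B number of bins.
#' @return numeric weights.
#' @export
balanced_weights <- function(bins, B = max(bins) + 1L) {
  cnt <- tabulate(bins + 1L, B)
  w <- 1 / cnt[bins + 1L]
  w * length(bins) / sum(w)
}

#' Bin probabilities under a fitted link
#' @param link a `logistic_link`.
#' @param x numeric phenotypes (log10 P_on).
#' @return matrix `length(x)` x B of bin probabilities.
#' @export
bin_probabilities <- function(link, x) {
  Z <- outer(x, link$a) + matrix(link$b, length(x), link$B, byrow = TRUE)
  S <- 1 / (1 + exp(-Z))
  S / rowSums(S)
}

#' Measurable-expression cutoff from a fitted link
#'
#' The phenotype at which the two lowest bins are equiprobable
#' (pi_0 = pi_1), i.e. the model-space image of the instrument
#' detectability threshold.
#'
#' @param link a `logistic_link`.
#' @param bins the two bin indices to equate (default 0 and 1).
#' @return x (log10 P_on) at the crossing.
#' @export
measurable_cutoff <- function(link, bins = c(0L, 1L)) {
  i <- bins + 1L
  (link$b[i[2]] - link$b[i[1]]) / (link$a[i[1]] - link$a[i[2]])
}

#' Weighted coefficient of determination
#'
#' Squared weighted Pearson correlation between prediction and
#' observation, using the same weights as the logistic regression.
#'
#' @param x,y numeric vectors.
#' @param w weights.
#' @return r-squared in [0, 1].
#' @export
weighted_r2 <- function(x, y, w = rep(1, length(x))) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]; w <- w[keep] / sum(w[keep])
  mx <- sum(w * x); my <- sum(w * y)
  cxy <- sum(w * (x - mx) * (y - my))
  cxy^2 / (sum(w * (x - mx)^2) * sum(w * (y - my)^2))
}

## ---- internal fitting machinery ------------------------------------------

# Precompute the per-library structures the C++ likelihood needs.
fit_data <- function(lib, mode = NULL) {
  y <- observed_bin(lib, mode)
  keep <- !is.na(y)
  codes <- lapply(lib$sequences[keep], encode_dna)
  rbs <- rep(if (is.na(lib$rbs_start)) -1L else lib$rbs_start - 1L,
             sum(keep))
  B <- ncol(lib$counts)
  y <- y[keep]
  list(codes = codes, rbs = rbs, y = y, wgt = balanced_weights(y, B), B = B,
       n = sum(keep))
}

# Likelihood (and gradient) of the data under (model, link, features).
model_loglik <- function(data, model, link, features, want_grad = FALSE,
                         deltas_only = FALSE) {
  fl <- if (length(features)) feature_flags(model, features) else
    list(sum_mode = FALSE, use_spen = FALSE, use_occl = FALSE,
         use_rc = FALSE, use_dinuc = FALSE, R = 0)
  dn <- dinuc_cpp(model)
  cpp_loglik(data$codes, data$rbs, model$upstream, model$downstream,
             as.integer(names(model$spacer_penalties)),
             unname(model$spacer_penalties), dn$pos, dn$de, model$mu, fl$R,
             model$rbs_occlusion_cutoff, fl$sum_mode, fl$use_spen,
             fl$use_occl, fl$use_rc, fl$use_dinuc, data$y, data$wgt,
             link$a, link$b, want_grad, deltas_only)
}

pack_params <- function(model, what) {
  th <- c()
  if ("matrix" %in% what) th <- c(th, as.numeric(model$upstream),
                                  as.numeric(model$downstream))
  if ("spacer" %in% what) th <- c(th, unname(model$spacer_penalties))
  if ("mu" %in% what) th <- c(th, model$mu)
  if ("dinuc" %in% what) th <- c(th, model$dinucleotides$delta_e)
  th
}

unpack_params <- function(theta, model, what) {
  i <- 0L
  if ("matrix" %in% what) {
    n35 <- length(model$upstream); n10 <- length(model$downstream)
    model$upstream[] <- theta[i + seq_len(n35)]; i <- i + n35
    model$downstream[] <- theta[i + seq_len(n10)]; i <- i + n10
  }
  if ("spacer" %in% what) {
    ns <- length(model$spacer_penalties)
    model$spacer_penalties[] <- theta[i + seq_len(ns)]; i <- i + ns
  }
  if ("mu" %in% what) { model$mu <- theta[i + 1L]; i <- i + 1L }
  if ("dinuc" %in% what)
    model$dinucleotides$delta_e <- theta[i + seq_len(nrow(model$dinucleotides))]
  model
}

param_bounds <- function(model, what) {
  lo <- c(); hi <- c()
  if ("matrix" %in% what) {
    k <- length(model$upstream) + length(model$downstream)
    lo <- c(lo, rep(0, k)); hi <- c(hi, rep(12, k))
  }
  if ("spacer" %in% what) {
    ns <- length(model$spacer_penalties)
    lo <- c(lo, rep(0, ns)); hi <- c(hi, rep(12, ns))
  }
  if ("mu" %in% what) { lo <- c(lo, -30); hi <- c(hi, 2) }
  if ("dinuc" %in% what) {
    nd <- nrow(model$dinucleotides)
    lo <- c(lo, rep(-2, nd)); hi <- c(hi, rep(2, nd))
  }
  list(lower = lo, upper = hi)
}

pack_grad <- function(gl, model, what) {
  g <- c()
  if ("matrix" %in% what) g <- c(g, as.numeric(gl$grad_up),
                                 as.numeric(gl$grad_down))
  if ("spacer" %in% what) g <- c(g, gl$grad_spacer)
  if ("mu" %in% what) g <- c(g, gl$grad_mu)
  if ("dinuc" %in% what) g <- c(g, gl$grad_delta)
  g
}

# One feature stage: bounded quasi-Newton jointly over the energy
# parameters and the link coefficients (with analytic gradients from the
# compiled core), polished by a clean link refit and repeated until the
# joint likelihood stops improving.
fit_stage <- function(data, model, features, what, link = NULL,
                      control = fit_control()) {
  B <- data$B
  if (is.null(link)) {
    x <- model_loglik(data, model, list(a = rep(0, B), b = rep(0, B)),
                      features)$x
    link <- fit_logistic(x, data$y, data$wgt, B = B)
  }
  ll_old <- -Inf
  ll_new <- link$loglik
  converged <- FALSE
  deltas_only <- identical(what, "dinuc")
  np <- length(pack_params(model, what))
  for (outer in seq_len(control$max_outer)) {
    cache <- new.env()
    fngr <- function(theta) {
      key <- paste(theta, collapse = ",")
      if (!identical(cache$key, key)) {
        m2 <- unpack_params(theta[seq_len(np)], model, what)
        lk <- list(a = theta[np + 1:B], b = theta[np + B + 1:B])
        gl <- model_loglik(data, m2, lk, features, want_grad = TRUE,
                           deltas_only = deltas_only)
        cache$key <- key; cache$ll <- gl$ll
        cache$gr <- c(pack_grad(gl, m2, what), gl$grad_a, gl$grad_b)
      }
      invisible(NULL)
    }
    bd <- param_bounds(model, what)
    opt <- stats::optim(c(pack_params(model, what), link$a, link$b),
                        fn = function(th) { fngr(th); cache$ll },
                        gr = function(th) { fngr(th); cache$gr },
                        method = "L-BFGS-B",
                        lower = c(bd$lower, rep(-1000, 2 * B)),
                        upper = c(bd$upper, rep(1000, 2 * B)),
                        control = list(fnscale = -1,
                                       maxit = control$maxit))
    model <- unpack_params(opt$par[seq_len(np)], model, what)
    # re-pin the gauge (column minima to zero, mu compensating) so the
    # flat gauge direction cannot drift against the box bounds
    if ("matrix" %in% what) model <- normalize_energy_model(model)
    x <- model_loglik(data, model, link, features)$x
    link <- fit_logistic(x, data$y, data$wgt, B = B)
    ll_new <- link$loglik
    if (ll_new - ll_old < control$outer_tol) { converged <- TRUE; break }
    ll_old <- ll_new
  }
  list(model = model, link = link, loglik = ll_new, x = x,
       converged = converged)
}

#' Optimization control settings
#'
#' @param outer_tol stop when the joint log-likelihood improves by less
#'   than this between outer (energy/link) alternations (default 1e-6).
#' @param max_outer maximum outer alternations (default 200).
#' @param maxit L-BFGS-B iterations per inner solve (default 100).
#' @return list of settings.
#' @export
fit_control <- function(outer_tol = 1e-6, max_outer = 200L, maxit = 100L) {
  list(outer_tol = outer_tol, max_outer = max_outer, maxit = maxit)
}

#' Fit an energy model to a training library
#'
#' Maximizes the likelihood of the weighted multinomial logistic
#' regression of log10 P_on against the observed expression bin, starting
#' from the Standard model and adding the requested structural features
#' sequentially, each stage warm-started in the vicinity of the previous
#' best fit. The validation split, when given, is only scored (model
#' selection), never optimized on; the evaluation split is not accepted
#' by this function at all (see [evaluate_fit()]).
#'
#' @param training a `sortseq_library`.
#' @param start starting `energy_model` (geometry fixes the footprint).
#' @param feature_set ordered subset of [extended_features()] to add on
#'   top of the Standard model.
#' @param validation optional `sortseq_library` scored per stage.
#' @param clearance_grid R grid for the clearance stage (must include 0).
#' @param control see [fit_control()].
#' @return a `fit_report`: the optimized (normalized) `energy_model`, the
#'   fitted link, per-stage feature ledger (log-likelihoods, weighted r2,
#'   variance-explained increments) and convergence flags.
#' @export
optimize_model <- function(training, start,
                           feature_set = c("spacer_penalty", "cumulative",
                                           "occlusive", "reverse_complement"),
                           validation = NULL,
                           clearance_grid = c(0, 0.1, 0.2, 0.3, 0.5, 1),
                           control = fit_control()) {
  if (length(feature_set))
    feature_set <- match.arg(feature_set, extended_features(),
                             several.ok = TRUE)
  data <- fit_data(training)
  vdata <- if (!is.null(validation)) fit_data(validation)
  model <- start
  stages <- list()
  link <- NULL
  conv <- TRUE
  score_stage <- function(feat_name, st, feats) {
    r2_tr <- weighted_r2(st$x, data$y, data$wgt)
    ll_val <- r2_val <- NA_real_
    if (!is.null(vdata)) {
      lv <- model_loglik(vdata, st$model, st$link, feats)
      ll_val <- lv$ll
      r2_val <- weighted_r2(lv$x, vdata$y, vdata$wgt)
    }
    data.frame(feature = feat_name, train_ll = st$loglik,
               train_r2 = r2_tr, val_ll = ll_val, val_r2 = r2_val)
  }
  # stage 0: Standard model (single strongest site)
  st <- fit_stage(data, model, character(), c("matrix", "mu"), link, control)
  model <- st$model; link <- st$link; conv <- conv && st$converged
  stages[[1]] <- score_stage("standard", st, character())
  feats <- character()
  for (f in feature_set) {
    feats <- c(feats, f)
    if (f == "clearance") {
      sc <- scan_clearance_rate(training, model, clearance_grid,
                                features = feats, link = link,
                                control = control, data = data)
      model <- sc$model; link <- sc$link
      st <- list(model = model, link = link, loglik = sc$best_loglik,
                 x = sc$x, converged = TRUE)
    } else if (f == "dinucleotides" && nrow(model$dinucleotides) == 0) {
      # nothing to fit without a candidate table; record a no-op stage
      st <- list(model = model, link = link, loglik = link$loglik,
                 x = model_loglik(data, model, link, feats)$x,
                 converged = TRUE)
    } else {
      what <- c("matrix", "mu",
                if ("spacer_penalty" %in% feats) "spacer",
                if (f == "dinucleotides") "dinuc")
      st <- fit_stage(data, model, feats, what, link, control)
      model <- st$model; link <- st$link; conv <- conv && st$converged
    }
    stages[[length(stages) + 1]] <- score_stage(f, st, feats)
  }
  ledger <- do.call(rbind, stages)
  ledger$delta_val_r2 <- c(NA, diff(ledger$val_r2))
  model <- normalize_energy_model(model)
  structure(list(model = model, link = link, features = feats,
                 stages = ledger,
                 loglik = list(training = ledger$train_ll[nrow(ledger)],
                               validation = ledger$val_ll[nrow(ledger)]),
                 r2 = list(training = ledger$train_r2[nrow(ledger)],
                           validation = ledger$val_r2[nrow(ledger)]),
                 converged = conv),
            class = "fit_report")
}

#' @export
print.fit_report <- function(x, ...) {
  cat("Promoter-model fit report\n")
  print(x$stages, row.names = FALSE)
  cat(sprintf("converged: %s\n", x$converged))
  invisible(x)
}

#' Final evaluation of a fit on held-out data
#'
#' Scores a finished [optimize_model()] report on the evaluation split.
#' This is the only function that touches evaluation data.
#'
#' @param report a `fit_report`.
#' @param evaluation a `sortseq_library`.
#' @return the report with `$evaluation` (log-likelihood and weighted r2)
#'   filled in.
#' @export
evaluate_fit <- function(report, evaluation) {
  edata <- fit_data(evaluation)
  le <- model_loglik(edata, report$model, report$link, report$features)
  report$evaluation <- list(loglik = le$ll,
                            r2 = weighted_r2(le$x, edata$y, edata$wgt))
  report
}

# Multi-library variant of fit_stage: one shared energy model, one link
# per library (which also absorbs per-library chemical-potential
# offsets), maximizing the summed log-likelihood.
fit_stage_multi <- function(datas, model, features, what, links = NULL,
                            control = fit_control()) {
  K <- length(datas)
  if (is.null(links)) links <- lapply(datas, function(d) {
    x <- model_loglik(d, model, list(a = rep(0, d$B), b = rep(0, d$B)),
                      features)$x
    fit_logistic(x, d$y, d$wgt, B = d$B)
  })
  np <- length(pack_params(model, what))
  Bs <- vapply(datas, `[[`, 0L, "B")
  off <- np + c(0L, cumsum(2L * Bs))
  deltas_only <- identical(what, "dinuc")
  ll_old <- -Inf
  ll_new <- sum(vapply(links, `[[`, 0, "loglik"))
  # the warm start is a fallback: a joint round that ends worse than the
  # best state seen so far is discarded
  best <- list(model = model, links = links, loglik = ll_new)
  converged <- FALSE
  for (outer in seq_len(control$max_outer)) {
    cache <- new.env()
    fngr <- function(theta) {
      key <- paste(theta, collapse = ",")
      if (!identical(cache$key, key)) {
        m2 <- unpack_params(theta[seq_len(np)], model, what)
        ll <- 0; gsh <- 0; glk <- c()
        for (k in seq_len(K)) {
          lk <- list(a = theta[off[k] + 1:Bs[k]],
                     b = theta[off[k] + Bs[k] + 1:Bs[k]])
          gl <- model_loglik(datas[[k]], m2, lk, features,
                             want_grad = TRUE, deltas_only = deltas_only)
          ll <- ll + gl$ll
          gsh <- gsh + pack_grad(gl, m2, what)
          glk <- c(glk, gl$grad_a, gl$grad_b)
        }
        cache$key <- key; cache$ll <- ll; cache$gr <- c(gsh, glk)
      }
      invisible(NULL)
    }
    bd <- param_bounds(model, what)
    th0 <- c(pack_params(model, what),
             unlist(lapply(links, function(l) c(l$a, l$b))))
    nl <- length(th0) - np
    opt <- stats::optim(th0,
                        fn = function(th) { fngr(th); cache$ll },
                        gr = function(th) { fngr(th); cache$gr },
                        method = "L-BFGS-B",
                        lower = c(bd$lower, rep(-1000, nl)),
                        upper = c(bd$upper, rep(1000, nl)),
                        control = list(fnscale = -1,
                                       maxit = control$maxit))
    model <- unpack_params(opt$par[seq_len(np)], model, what)
    if ("matrix" %in% what) model <- normalize_energy_model(model)
    links <- lapply(seq_len(K), function(k) {
      x <- model_loglik(datas[[k]], model, links[[k]], features)$x
      fit_logistic(x, datas[[k]]$y, datas[[k]]$wgt, B = Bs[k])
    })
    ll_new <- sum(vapply(links, `[[`, 0, "loglik"))
    if (ll_new > best$loglik)
      best <- list(model = model, links = links, loglik = ll_new)
    if (ll_new - ll_old < control$outer_tol) { converged <- TRUE; break }
    ll_old <- ll_new
  }
  list(model = best$model, links = best$links, link = best$links[[1]],
       loglik = best$loglik, converged = converged)
}

#' Refit a model's energy parameters in place
#'
#' A single joint maximum-likelihood solve (matrix, spacer penalties,
#' chemical potential, any dinucleotide terms the model carries, and the
#' links) under a fixed feature set, warm-started from the given model.
#' With a list of libraries the summed log-likelihood is maximized with
#' one link per library (pooled refitting: this is how a model fitted on
#' a local library is polished against additional libraries before and
#' after dinucleotide selection).
#'
#' @param training a `sortseq_library`, or a list of them (pooled fit).
#' @param model the warm-start `energy_model`.
#' @param features structural features in force.
#' @param control see [fit_control()].
#' @return list with the refit (normalized) `model`, `link` (first
#'   library), `links` (all libraries), `loglik` and convergence flag.
#' @export
refit_energy_model <- function(training, model,
                               features = extended_features(),
                               control = fit_control()) {
  if (inherits(training, "sortseq_library")) training <- list(training)
  datas <- lapply(training, fit_data)
  what <- c("matrix", "mu",
            if ("spacer_penalty" %in% features) "spacer",
            if ("dinucleotides" %in% features &&
                  nrow(model$dinucleotides) > 0) "dinuc")
  fit_stage_multi(datas, model, features, what, NULL, control)
}

#' Profile the clearance rate
#'
#' Scans a grid of relative clearance rates R; for each value the
#' chemical potential (and the link) is refit on the training data and
#' the training log-likelihood recorded. R is completely degenerate with
#' mu for single-site sequences, so a flat profile is expected unless
#' strong multi-site binding is present.
#'
#' @param training a `sortseq_library`.
#' @param model the current `energy_model`.
#' @param grid R values; must include 0.
#' @param features feature set in force (default full Extended set).
#' @param link optional current link (refit per R regardless).
#' @param control see [fit_control()].
#' @param data internal precomputed fit data.
#' @return list with `profile` (data frame R/loglik), `best_R`, the
#'   refitted `model`, `link`, `x`, and `best_loglik`.
#' @export
scan_clearance_rate <- function(training, model, grid = c(0, 0.1, 0.2, 0.3,
                                                          0.5, 1),
                                features = extended_features(), link = NULL,
                                control = fit_control(), data = NULL) {
  stopifnot(0 %in% grid)
  if (is.null(data)) data <- fit_data(training)
  ctl <- control; ctl$max_outer <- min(ctl$max_outer, 20L)
  res <- lapply(grid, function(R) {
    m <- model; m$clearance_rate <- R
    fit_stage(data, m, features, "mu", link, ctl)
  })
  ll <- vapply(res, `[[`, 0, "loglik")
  best <- which.max(ll)
  list(profile = data.frame(R = grid, loglik = ll), best_R = grid[best],
       model = res[[best]]$model, link = res[[best]]$link,
       x = res[[best]]$x, best_loglik = ll[best])
}
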