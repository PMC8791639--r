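#' All candidate dinucleotide interactions
#'
#' Every (position, base, position, base) pair over the contact footprint
#' (positions 1..L35+L10, upstream block first), giving
#' C(n_contacts, 2) * 16 candidates (4416 for 24 contacts). The row order
#' is the canonical candidate order used by the profiling scan.
#'
#' @param model an `energy_model` (footprint geometry).
#' @return data frame with columns `pos_i`, `base_i`, `pos_j`, `base_j`.
#' @export
dinuc_candidates <- function(model) {
  nct <- ncol(model$upstream) + ncol(model$downstream)
  pairs <- do.call(rbind, lapply(seq_len(nct - 1), function(k)
    cbind(k, (k + 1):nct)))
  np <- nrow(pairs)
  data.frame(pos_i = rep(pairs[, 1], each = 16L),
             base_i = rep(rep(DNA_BASES, each = 4L), np),
             pos_j = rep(pairs[, 2], each = 16L),
             base_j = rep(DNA_BASES, 4L * np),
             stringsAsFactors = FALSE)
}

# Per-library fitting context for the selection funnel: fit data, the
# baseline phenotype and link under the current model, and the pruned
# configuration extract for fast candidate profiling.
dinuc_context <- function(lib, model, features, fl, dn, prune_frac) {
  data <- fit_data(lib)
  x <- model_loglik(data, model, list(a = rep(0, data$B),
                                      b = rep(0, data$B)), features)$x
  link <- fit_logistic(x, data$y, data$wgt, B = data$B)
  pe <- cpp_prune_extract(data$codes, data$rbs, model$upstream,
                          model$downstream,
                          as.integer(names(model$spacer_penalties)),
                          unname(model$spacer_penalties), dn$pos, dn$de,
                          model$mu, fl$R, model$rbs_occlusion_cutoff,
                          fl$use_spen, fl$use_occl, fl$use_rc, fl$use_dinuc,
                          prune_frac)
  list(data = data, link = link, pe = pe)
}

# Restrict a fit-data context to a subset of records.
slice_data <- function(data, idx) {
  d <- list(codes = data$codes[idx], rbs = data$rbs[idx], y = data$y[idx],
            B = data$B, n = length(idx))
  d$wgt <- balanced_weights(d$y, d$B)
  d
}

# Joint maximum-likelihood fit of the interaction energies of `cands`
# over one or more libraries (all other parameters and the per-library
# links held fixed), optionally with an L1 penalty.  Returns the fitted
# delta vector.
fit_deltas <- function(datas, model, cands, features, links, lambda = 0,
                       init = NULL, maxit = 40L) {
  if (!is.null(datas$codes)) { datas <- list(datas); links <- list(links) }
  nd <- nrow(cands)
  fl <- feature_flags(model, union(features, "dinucleotides"))
  dn <- dinuc_cpp(model)
  candm <- cbind(cands$pos_i - 1L, match(cands$base_i, DNA_BASES) - 1L,
                 cands$pos_j - 1L, match(cands$base_j, DNA_BASES) - 1L)
  storage.mode(candm) <- "integer"
  exs <- lapply(datas, function(d)
    cpp_subset_extract(d$codes, d$rbs, model$upstream, model$downstream,
                       as.integer(names(model$spacer_penalties)),
                       unname(model$spacer_penalties), dn$pos, dn$de,
                       model$mu, fl$R, model$rbs_occlusion_cutoff,
                       fl$use_spen, fl$use_occl, fl$use_rc, fl$use_dinuc,
                       candm))
  cache <- new.env()
  eval_at <- function(delta) {
    key <- paste(delta, collapse = ",")
    if (!identical(cache$key, key)) {
      ll <- 0; gr <- numeric(nd)
      for (k in seq_along(exs)) {
        ex <- exs[[k]]; d <- datas[[k]]; lk <- links[[k]]
        gl <- cpp_subset_llgrad(ex$t0, ex$klass, ex$seq_ptr, ex$match_cfg,
                                ex$match_cand, delta, fl$R, d$y, d$wgt,
                                lk$a, lk$b, TRUE)
        ll <- ll + gl$ll; gr <- gr + gl$grad_delta
      }
      cache$key <- key; cache$ll <- ll; cache$gr <- gr
    }
    invisible(NULL)
  }
  if (lambda > 0) {
    # doubled-variable parameterization delta = p - q keeps the objective
    # smooth under L-BFGS-B
    fn <- function(th) {
      d <- th[1:nd] - th[nd + 1:nd]; eval_at(d)
      cache$ll - lambda * sum(th)
    }
    gr <- function(th) {
      d <- th[1:nd] - th[nd + 1:nd]; eval_at(d)
      c(cache$gr - lambda, -cache$gr - lambda)
    }
    d0 <- if (is.null(init)) rep(0, nd) else init
    th0 <- c(pmax(d0, 0), pmax(-d0, 0))
    opt <- stats::optim(th0, fn, gr, method = "L-BFGS-B",
                        lower = rep(0, 2 * nd), upper = rep(2, 2 * nd),
                        control = list(fnscale = -1, maxit = maxit))
    opt$par[1:nd] - opt$par[nd + 1:nd]
  } else {
    fn <- function(d) { eval_at(d); cache$ll }
    gr <- function(d) { eval_at(d); cache$gr }
    d0 <- if (is.null(init)) rep(0, nd) else init
    opt <- stats::optim(d0, fn, gr, method = "L-BFGS-B",
                        lower = rep(-2, nd), upper = rep(2, nd),
                        control = list(fnscale = -1, maxit = maxit))
    opt$par
  }
}

#' Staged selection of dinucleotide interactions
#'
#' Implements the funnel that reduces the full candidate set to a small
#' set of significant interaction energies between RNAP contact
#' positions. Interaction energies are weakly identifiable from a local
#' mutant library alone (an additive refit absorbs most of the pairwise
#' signal when wildtype residues dominate the base usage), so the funnel
#' accepts one *or several* libraries — typically a local mutant library
#' pooled with a fully random one — and maximizes the summed
#' log-likelihood, each library keeping its own baseline link.
#'
#' 1. every candidate's exact likelihood-improvement profile is evaluated
#'    on a grid of interaction energies (summed over libraries; computed
#'    on weight-pruned configuration sets); candidates improving the
#'    log-likelihood by at least `ll_threshold` nats survive;
#' 2. survivors are jointly re-estimated with L1 regularization in
#'    `n_backgrounds` random subsets of `subset_size`, each on random
#'    50:50 splits of the pooled training+validation data (the held-out
#'    halves pick the L1 strength); per candidate, estimates larger in
#'    magnitude than `accept_threshold` are combined into mean and sd,
#'    and candidates incompatible with zero at 2 sigma survive;
#' 3. the same with `stage3_backgrounds` unpenalized joint fits of
#'    subsets of `stage3_size`, at 3 sigma;
#' 4. survivors are included sequentially, most significant first, each
#'    required to remain 3-sigma-incompatible with zero in a joint refit
#'    against all interactions accepted so far.
#'
#' @param training,validation `sortseq_library` splits, or lists of them
#'   (one per pooled library).
#' @param model the fitted `energy_model` the candidates extend.
#' @param features structural features in force (default all but
#'   clearance).
#' @param accept_threshold minimum |delta E| (kB*T) for a stage-2
#'   estimate to count (default 0.002).
#' @param ll_threshold stage-1 log-likelihood improvement in nats
#'   (default 2).
#' @param delta_grid interaction energies at which stage-1 profiles are
#'   evaluated.
#' @param n_backgrounds,subset_size stage-2 joint-fit design (default
#'   10 subsets of 20).
#' @param stage3_backgrounds,stage3_size stage-3 design (default 12
#'   subsets of 50).
#' @param lambda_grid L1 strengths tried in stage 2 (chosen by held-out
#'   likelihood).
#' @param prune_frac configurations below this fraction of a sequence's
#'   largest Boltzmann weight are dropped from stage-1 profiling.
#' @param stage2_cap stage-1 survivors carried into the joint stages are
#'   capped at this many, strongest improvements first (default 200).
#' @param seed RNG seed for subset draws and CV splits.
#' @param control see [fit_control()].
#' @return data frame of accepted interactions (`pos_i`, `base_i`,
#'   `pos_j`, `base_j`, `delta_e`, `sd`), with the per-stage candidate
#'   counts in `attr(, "funnel")`.
#' @export
select_dinucleotides <- function(training, validation, model,
                                 features = setdiff(extended_features(),
                                                    c("clearance",
                                                      "dinucleotides")),
                                 accept_threshold = 0.002, ll_threshold = 2,
                                 delta_grid = seq(-0.6, 0.6, by = 0.1),
                                 n_backgrounds = 10L,
                                 subset_size = 20L, stage3_backgrounds = 12L,
                                 stage3_size = 50L,
                                 lambda_grid = c(0.5, 2), prune_frac = 1e-6,
                                 stage2_cap = 200L, seed = 1L,
                                 control = fit_control()) {
  set.seed(seed)
  trainings <- if (inherits(training, "sortseq_library")) list(training)
               else training
  validations <- if (inherits(validation, "sortseq_library"))
                   list(validation) else validation
  stopifnot(length(trainings) == length(validations))
  fl <- feature_flags(model, c(features, "dinucleotides"))
  dn <- dinuc_cpp(model)
  ctx <- lapply(trainings, dinuc_context, model = model,
                features = features, fl = fl, dn = dn,
                prune_frac = prune_frac)
  cands <- dinuc_candidates(model)
  funnel <- c(candidates = nrow(cands))
  empty <- cbind(empty_dinucleotides(), sd = numeric())
  delta_grid <- setdiff(delta_grid, 0)

  ## stage 1: exact grid profiles, summed over libraries
  dll <- 0
  for (cx in ctx) {
    dll <- dll + cpp_stage1_grid(cx$pe$S_on, cx$pe$S_np, cx$pe$t, cx$pe$on,
                                 cx$pe$seq, cx$pe$contacts, cx$data$y,
                                 cx$data$wgt, cx$link$a, cx$link$b, fl$R,
                                 delta_grid)
  }
  best_g <- max.col(dll, ties.method = "first")
  best_dll <- dll[cbind(seq_len(nrow(dll)), best_g)]
  keep1 <- best_dll >= ll_threshold
  surv <- cands[keep1, , drop = FALSE]
  surv$delta1 <- delta_grid[best_g[keep1]]
  surv$dll1 <- best_dll[keep1]
  funnel["stage1"] <- nrow(surv)
  if (!nrow(surv)) return(structure(empty, funnel = funnel))
  if (nrow(surv) > stage2_cap) {
    # a very deep stage-1 field signals residual additive misfit; carry
    # forward the strongest improvements only
    surv <- surv[order(-surv$dll1)[seq_len(stage2_cap)], , drop = FALSE]
    funnel["stage1_capped"] <- nrow(surv)
  }

  ## pooled per-library data (training + validation) for CV splits
  pools <- lapply(seq_along(trainings), function(k) {
    dt <- ctx[[k]]$data
    dv <- fit_data(validations[[k]])
    d <- list(codes = c(dt$codes, dv$codes), rbs = c(dt$rbs, dv$rbs),
              y = c(dt$y, dv$y), B = dt$B)
    d$wgt <- balanced_weights(d$y, d$B)
    d$n <- length(d$y)
    d
  })
  links <- lapply(ctx, `[[`, "link")
  n_total <- sum(vapply(pools, `[[`, 0L, "n"))

  joint_stage <- function(surv, n_bg, size, sigma, use_l1) {
    if (n_total < 10L * max(vapply(pools, `[[`, 0L, "B"))) {
      warning("training set too small for joint dinucleotide stage; skipped")
      surv$sd <- rep(1e-6, nrow(surv))
      return(surv)
    }
    est <- vector("list", n_bg)
    for (bg in seq_len(n_bg)) {
      sub <- sort(sample.int(nrow(surv), min(size, nrow(surv))))
      halves <- lapply(pools, function(p) {
        idx <- sample.int(p$n, p$n %/% 2)
        list(A = slice_data(p, idx),
             B = slice_data(p, setdiff(seq_len(p$n), idx)))
      })
      dA <- lapply(halves, `[[`, "A")
      dB <- lapply(halves, `[[`, "B")
      cands_bg <- surv[sub, , drop = FALSE]
      init <- surv$delta1[sub]
      if (use_l1) {
        best <- NULL; best_ll <- -Inf
        for (lam in lambda_grid) {
          dl <- fit_deltas(dA, model, cands_bg, features, links,
                           lambda = lam, init = init)
          m2 <- model
          m2$dinucleotides <- data.frame(
            cands_bg[, c("pos_i", "base_i", "pos_j", "base_j")],
            delta_e = dl, stringsAsFactors = FALSE)
          llB <- sum(vapply(seq_along(dB), function(k)
            model_loglik(dB[[k]], m2, links[[k]],
                         union(features, "dinucleotides"))$ll, 0))
          if (llB > best_ll) { best_ll <- llB; best <- dl }
        }
        dl <- best
      } else {
        dl <- fit_deltas(dA, model, cands_bg, features, links,
                         lambda = 0, init = init)
      }
      est[[bg]] <- data.frame(cand = sub, delta = dl)
    }
    est <- do.call(rbind, est)
    est <- est[abs(est$delta) > accept_threshold, , drop = FALSE]
    mu_sd <- t(vapply(seq_len(nrow(surv)), function(ci) {
      d <- est$delta[est$cand == ci]
      if (length(d) < 2) return(c(NA_real_, NA_real_))
      c(mean(d), max(stats::sd(d), 1e-6))
    }, numeric(2)))
    keep <- !is.na(mu_sd[, 1]) & abs(mu_sd[, 1]) > sigma * mu_sd[, 2]
    out <- surv[keep, , drop = FALSE]
    out$delta1 <- mu_sd[keep, 1]
    out$sd <- mu_sd[keep, 2]
    out
  }

  ## stage 2: L1 joint fits in random backgrounds, 2 sigma
  surv <- joint_stage(surv, n_backgrounds, subset_size, 2, use_l1 = TRUE)
  funnel["stage2"] <- nrow(surv)
  if (!nrow(surv)) return(structure(empty, funnel = funnel))

  ## stage 3: unpenalized joint fits, 3 sigma
  surv <- joint_stage(surv, stage3_backgrounds, stage3_size, 3,
                      use_l1 = FALSE)
  funnel["stage3"] <- nrow(surv)
  if (!nrow(surv)) return(structure(empty, funnel = funnel))

  ## stage 4: sequential inclusion, most significant first, 3 sigma in the
  ## background of everything accepted so far
  surv <- surv[order(abs(surv$delta1) / surv$sd, decreasing = TRUE), ,
               drop = FALSE]
  train_datas <- lapply(ctx, `[[`, "data")
  accepted <- surv[0, , drop = FALSE]
  for (i in seq_len(nrow(surv))) {
    trial <- rbind(accepted, surv[i, ])
    dl <- fit_deltas(train_datas, model, trial, features, links,
                     lambda = 0, init = trial$delta1)
    if (abs(dl[nrow(trial)]) > 3 * surv$sd[i]) {
      accepted <- trial
      accepted$delta1 <- dl
    }
  }
  funnel["accepted"] <- nrow(accepted)
  out <- data.frame(accepted[, c("pos_i", "base_i", "pos_j", "base_j")],
                    delta_e = accepted$delta1, sd = accepted$sd,
                    stringsAsFactors = FALSE)
  structure(out, funnel = funnel)
}
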