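## Mechanism-structure identification: greedy forward selection with a
## confirmatory backward elimination round.

default_stop_rule <- function() {
  list(min_rel_reduction = 0.01,  # accept a round only if OBJ falls >= 1%
       use_spread = TRUE)         # ... and by more than the multistart spread
}

#' Forward selection of ET-1 effect mechanisms
#'
#' Starting from the NULL model (no ET-1 effects), each round fits every
#' remaining candidate mechanism and functional form in combination with the
#' mechanisms already kept, keeps the single candidate producing the largest
#' objective reduction, and jointly refits all kept parameters. Rounds
#' continue until the best reduction fails the stop rule (relative reduction
#' below `min_rel_reduction`, or not exceeding the multistart spread of the
#' refit). At equal objective a linear candidate is preferred over a
#' sigmoidal one (fewer parameters).
#'
#' @param candidates Candidate templates from [candidate_set()].
#' @param observations An [observation_table()].
#' @param config An `et_config`.
#' @param stop_rule List with `min_rel_reduction` and `use_spread`.
#' @param screen `"hybrid"` (default): every candidate is first screened
#'   cheaply by fitting only its own parameters with the kept slopes frozen
#'   (after a coarse grid scan of the candidate slope); the `shortlist_k`
#'   best candidates are then re-screened by a joint refit with all kept
#'   mechanisms, which resolves the rank distortions frozen-parameter
#'   screening can produce among collinear candidates. `"refit"` screens
#'   every candidate by a joint refit; `"fixed"` uses the frozen screen
#'   alone. In all modes the round's winner is refit jointly with a
#'   multi-start polish and that objective is recorded.
#' @param shortlist_k Number of top candidates promoted to joint-refit
#'   screening under the hybrid mode.
#' @param n_starts_screen,n_starts_refit Optimizer starts for screening and
#'   for the winner's joint refit.
#' @param maxit_screen,maxit_refit Optimizer iteration caps for screening
#'   fits and joint refits.
#' @param rtol,atol ODE solver tolerances used during selection (defaults:
#'   rtol 1e-5 / atol 1e-8, slightly looser than the simulation defaults;
#'   the screening ranks and refit objectives are insensitive at this
#'   level).
#' @param tie_tol Relative objective difference below which linear and
#'   sigmoidal fits of one candidate count as tied.
#' @param seed Seed for start jitter.
#' @param max_rounds Cap on accepted rounds.
#' @param verbose Print per-round progress.
#' @return A list of class `et_selection_trace`: `rounds` (one row per
#'   accepted round with fitted slope, OBJ and the percent reductions from
#'   the NULL model and from the previous round), `screening` (per-round
#'   candidate tables), `mechanisms` (final selected set with jointly
#'   refitted parameters), `fit` (final [fit_parameters()] result),
#'   `OBJ_null`, and `stopped_because`.
#' @export
forward_select <- function(candidates = candidate_set(), observations,
                           config = et_config(),
                           stop_rule = default_stop_rule(),
                           screen = c("hybrid", "refit", "fixed"),
                           shortlist_k = 3,
                           n_starts_screen = 1, n_starts_refit = 2,
                           maxit_screen = 7, maxit_refit = 50,
                           tie_tol = 1e-3, seed = 1L,
                           max_rounds = length(candidates),
                           rtol = 1e-5, atol = 1e-8,
                           verbose = FALSE) {
  screen <- match.arg(screen)
  forms <- attr(candidates, "forms")
  if (is.null(forms)) forms <- "linear"
  ctx <- objective_context(observations, config, rtol = rtol, atol = atol)
  OBJ_null <- objective_eval(list(), ctx)$OBJ
  kept <- list()
  OBJ_prev <- OBJ_null
  rounds <- list(); screening <- list()
  stopped <- "max_rounds reached"
  final_fit <- NULL

  if (length(candidates) == 0) {
    return(structure(list(rounds = data.frame(), screening = list(),
                          mechanisms = list(), fit = NULL,
                          OBJ_null = OBJ_null,
                          stopped_because = "empty candidate set"),
                     class = "et_selection_trace"))
  }

  for (round in seq_len(max_rounds)) {
    kept_keys <- vapply(kept, function(m) paste(m$receptor, m$target), "")
    remaining <- Filter(function(cand)
      !(paste(cand$receptor, cand$target) %in% kept_keys), candidates)
    if (length(remaining) == 0) { stopped <- "candidates exhausted"; break }

    tab <- data.frame()
    fits <- list()
    slope_grid <- c(-2, -0.5, -0.1, 0.1, 0.5, 2)
    OBJ_kept <- objective_eval(kept, ctx)$OBJ
    screen_one <- function(mech, joint) {
      ## coarse scan over the candidate slope picks a robust optimizer
      ## start (the clamped linear form makes zero starts fragile)
      grid_obj <- vapply(slope_grid, function(g) {
        mech$m <- g
        o <- objective_eval(c(kept, list(mech)), ctx)$OBJ
        if (is.finite(o)) o else 1e10
      }, 0)
      if (min(grid_obj) < OBJ_kept) mech$m <- slope_grid[which.min(grid_obj)]
      if (joint) {
        fit_parameters(c(kept, list(mech)), observations, config,
                       context = ctx, n_starts = n_starts_screen,
                       seed = seed, maxit = maxit_screen, method = "lm",
                       compute_se = FALSE)
      } else {
        fit_parameters(list(mech), observations, config,
                       fixed_mechanisms = kept, context = ctx,
                       n_starts = n_starts_screen, seed = seed,
                       maxit = maxit_screen, method = "lm",
                       compute_se = FALSE)
      }
    }
    for (cand in remaining) {
      for (form in forms) {
        mech <- mechanism(cand$receptor, cand$target, form, m = 0, b = 1)
        f <- screen_one(mech, joint = screen == "refit")
        key <- sprintf("%s:%s:%s", cand$receptor, cand$target, form)
        fits[[key]] <- f
        tab <- rbind(tab, data.frame(
          receptor = cand$receptor, target = cand$target, form = form,
          m = unname(f$par[if (screen == "refit") length(f$par) else 1]),
          OBJ = f$OBJ))
      }
    }
    if (screen == "hybrid") {
      ## promote the best candidates to joint-refit screening
      short_idx <- head(order(tab$OBJ), shortlist_k)
      for (r in short_idx) {
        mech <- mechanism(tab$receptor[r], tab$target[r], tab$form[r],
                          m = 0, b = 1)
        f <- screen_one(mech, joint = TRUE)
        key <- sprintf("%s:%s:%s", tab$receptor[r], tab$target[r],
                       tab$form[r])
        fits[[key]] <- f
        tab$OBJ[r] <- f$OBJ
        tab$m[r] <- unname(f$par[length(f$par)])
      }
      ## candidates not shortlisted keep their (pessimistic) frozen-screen
      ## objective; joint refits only lower the shortlisted objectives, so
      ## the round winner is always among the shortlisted
      tab$OBJ_joint <- FALSE
      tab$OBJ_joint[short_idx] <- TRUE
    }
    ## tie-break: within a (receptor, target), prefer linear unless the
    ## sigmoidal fit is better by more than tie_tol relative
    tab$OBJ_rank <- tab$OBJ
    if (all(c("linear", "sigmoidal") %in% forms)) {
      for (r in which(tab$form == "sigmoidal")) {
        lin <- which(tab$receptor == tab$receptor[r] &
                     tab$target == tab$target[r] & tab$form == "linear")
        if (length(lin) && tab$OBJ[r] >= tab$OBJ[lin] * (1 - tie_tol))
          tab$OBJ_rank[r] <- Inf
      }
    }
    best_i <- which.min(tab$OBJ_rank)
    best_key <- sprintf("%s:%s:%s", tab$receptor[best_i],
                        tab$target[best_i], tab$form[best_i])
    screening[[round]] <- tab[order(tab$OBJ), setdiff(names(tab), "OBJ_rank")]

    ## joint refit of the kept set plus the winner, warm-started
    wf <- fits[[best_key]]$mechanisms
    winner <- wf[[length(wf)]]
    refit <- fit_parameters(c(kept, list(winner)), observations, config,
                            context = ctx, n_starts = n_starts_refit,
                            seed = seed + round, maxit = maxit_refit,
                            method = "lm", compute_se = FALSE)
    OBJ_round <- min(refit$OBJ, fits[[best_key]]$OBJ)
    reduction <- OBJ_prev - OBJ_round
    rel <- reduction / OBJ_prev
    spread <- 0
    if (isTRUE(stop_rule$use_spread) && nrow(refit$starts) > 1) {
      v <- sort(refit$starts$OBJ[is.finite(refit$starts$OBJ)])
      if (length(v) > 1) spread <- v[2] - v[1]
    }
    accept <- rel >= stop_rule$min_rel_reduction && reduction > spread
    if (verbose)
      message(sprintf(
        "round %d: best %s, OBJ %.4g (%.2f%% reduction)%s", round,
        best_key, OBJ_round, 100 * rel,
        if (accept) "" else " -- rejected, stopping"))
    if (!accept) {
      stopped <- sprintf(
        "round %d best reduction %.3g%% failed the stop rule", round,
        100 * rel)
      break
    }
    kept <- refit$mechanisms
    final_fit <- refit
    rounds[[round]] <- data.frame(
      round = round, receptor = tab$receptor[best_i],
      target = tab$target[best_i], form = tab$form[best_i],
      m = unname(refit$par[length(refit$par)]),
      OBJ = OBJ_round,
      reduction_from_null_pct = 100 * (OBJ_round / OBJ_null - 1),
      reduction_from_prev_pct = 100 * (OBJ_round / OBJ_prev - 1))
    OBJ_prev <- OBJ_round
  }
  structure(list(rounds = do.call(rbind, rounds), screening = screening,
                 mechanisms = kept, fit = final_fit, OBJ_null = OBJ_null,
                 stopped_because = stopped),
            class = "et_selection_trace")
}

#' Backward elimination over a selected mechanism set
#'
#' Drops each mechanism in turn, refits the remainder, and records the
#' objective. Mechanisms whose removal does not increase the objective
#' beyond the stop-rule tolerance are flagged as unnecessary.
#'
#' @param mechanisms Selected mechanisms with fitted parameters (e.g.
#'   `forward_select(...)$mechanisms`).
#' @param observations An [observation_table()].
#' @param config An `et_config`.
#' @param stop_rule As in [forward_select()]; `min_rel_reduction` is the
#'   flagging tolerance.
#' @param n_starts,maxit,seed Optimizer settings for the drop refits.
#' @param rtol,atol ODE solver tolerances (as in [forward_select()]).
#' @return A list of class `et_backward`: `OBJ_full`, `table` (per-dropped
#'   mechanism OBJ and relative increase), `flagged` (mechanisms removable
#'   without objective penalty) and `confirmed` (the rest).
#' @export
backward_eliminate <- function(mechanisms, observations,
                               config = et_config(),
                               stop_rule = default_stop_rule(),
                               n_starts = 1, maxit = 50, seed = 1L,
                               rtol = 1e-5, atol = 1e-8) {
  if (length(mechanisms) == 0) stop("selected mechanism set is empty")
  ctx <- objective_context(observations, config, rtol = rtol, atol = atol)
  mechanisms <- anchor_mechanisms(mechanisms, ctx$occ0)
  OBJ_full <- objective_eval(mechanisms, ctx)$OBJ
  tab <- data.frame(); flagged <- c()
  for (k in seq_along(mechanisms)) {
    rest <- mechanisms[-k]
    OBJ_drop <- if (length(rest)) {
      fit_parameters(rest, observations, config, context = ctx,
                     n_starts = n_starts, seed = seed, maxit = maxit,
                     method = "lm", compute_se = FALSE)$OBJ
    } else {
      objective_eval(list(), ctx)$OBJ
    }
    rel_inc <- (OBJ_drop - OBJ_full) / OBJ_full
    necessary <- rel_inc > stop_rule$min_rel_reduction
    if (!necessary) flagged <- c(flagged, k)
    tab <- rbind(tab, data.frame(
      receptor = mechanisms[[k]]$receptor,
      target = mechanisms[[k]]$target,
      m = mechanisms[[k]]$m, OBJ_dropped = OBJ_drop,
      rel_increase = rel_inc, necessary = necessary))
  }
  structure(list(OBJ_full = OBJ_full, table = tab,
                 flagged = mechanisms[flagged],
                 confirmed = if (length(flagged)) mechanisms[-flagged]
                             else mechanisms),
            class = "et_backward")
}

#' @export
print.et_selection_trace <- function(x, ...) {
  cat(sprintf("Forward selection: NULL OBJ = %.4g\n", x$OBJ_null))
  if (!is.null(x$rounds) && nrow(x$rounds)) {
    print(x$rounds, row.names = FALSE, digits = 4)
  } else cat("  no mechanism accepted\n")
  cat("Stopped:", x$stopped_because, "\n")
  invisible(x)
}
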