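# Greedy SPR hill-climbing: standard (full alignment), Lasso-only, and
# two-phase search.
#
# Each iteration scores all SPR neighbors within the rearrangement radius
# lazily (no branch-length optimization; the regraft rule of spr_neighbors
# sets candidate lengths).  The first neighbor whose lazy score exceeds the
# current score by more than epsilon is accepted immediately and the scan
# restarts from it.  If no neighbor qualifies, branch lengths of the top_k
# best lazily-scored neighbors are fully optimized, in score order, and the
# first optimized candidate that beats the current tree by more than epsilon
# is accepted.  The search ends when neither stage yields an improvement.

# Internal driver.  scan_dat scores lazy candidates; opt_dat is used for
# branch-length optimization and optimized-candidate acceptance.  Offsets: a
# lasso evaluator adds its intercept so that traces are comparable across
# modes.
#
# Acceptance thresholds are running maxima (best lazy score seen, best
# optimized score seen).  When scan and optimization run on the same data
# they coincide with the current tree's scores and this is plain
# first-improvement hill climbing.  When they differ (phase 2 of the
# two-phase search: approximate scans, full-alignment optimization), a move
# accepted on one scale may lower the score on the other; holding each
# threshold at its running maximum keeps both acceptance sequences strictly
# increasing, which guarantees termination.
.spr_climb <- function(start, scan_dat, opt_dat, radius = 5, epsilon = 0.1,
                       top_k = 50, scan_offset = 0, opt_offset = 0,
                       counter = NULL, mode = "full") {
  cur <- optimize_branch_lengths(start, opt_dat, counter = counter)
  cur_opt <- attr(cur, "loglik") + opt_offset
  cur_scan <- total_log_likelihood(cur, scan_dat, counter = counter) +
    scan_offset
  moves <- 0L
  trace <- data.frame(move = 0L, ll = cur_opt, mode = "opt",
                      stringsAsFactors = FALSE)
  repeat {
    nbs <- spr_neighbors(cur, max_distance = radius)
    if (length(nbs) == 0) break
    scores <- rep(NA_real_, length(nbs))
    accepted <- FALSE
    for (i in seq_along(nbs)) {
      s <- total_log_likelihood(nbs[[i]]$tree, scan_dat, counter = counter) +
        scan_offset
      scores[i] <- s
      if (s > cur_scan + epsilon) {
        cur <- nbs[[i]]$tree
        cur_scan <- s
        moves <- moves + 1L
        trace <- rbind(trace, data.frame(move = moves, ll = s, mode = "lazy",
                                         stringsAsFactors = FALSE))
        accepted <- TRUE
        break
      }
    }
    if (accepted) next
    # stall: optimize the current tree, then the best-scored neighbors
    cur <- optimize_branch_lengths(cur, opt_dat, counter = counter)
    cur_opt <- max(cur_opt, attr(cur, "loglik") + opt_offset)
    cur_scan <- max(cur_scan,
                    total_log_likelihood(cur, scan_dat, counter = counter) +
                      scan_offset)
    ord <- order(-scores)
    ord <- ord[seq_len(min(top_k, length(ord)))]
    for (i in ord) {
      cand <- optimize_branch_lengths(nbs[[i]]$tree, opt_dat,
                                      counter = counter)
      cand_ll <- attr(cand, "loglik") + opt_offset
      if (cand_ll > cur_opt + epsilon) {
        cur <- cand
        cur_opt <- cand_ll
        cur_scan <- max(cur_scan,
                        total_log_likelihood(cur, scan_dat,
                                             counter = counter) +
                          scan_offset)
        moves <- moves + 1L
        trace <- rbind(trace, data.frame(move = moves, ll = cand_ll,
                                         mode = "opt",
                                         stringsAsFactors = FALSE))
        accepted <- TRUE
        break
      }
    }
    if (!accepted) break
  }
  cur <- optimize_branch_lengths(cur, opt_dat, counter = counter)
  trace$phase <- mode
  list(tree = cur, final_ll = attr(cur, "loglik") + opt_offset,
       trace = trace, n_moves = moves)
}

#' Greedy SPR hill-climbing tree search
#'
#' Standard search when `evaluator = "full"`; Lasso-only search when a
#' `lasso_sample` is supplied (all scoring, including the top-`top_k`
#' branch-length optimization, runs on the sampled sites with their Lasso
#' weights).  The reported final log-likelihood is always computed with all
#' alignment sites.
#'
#' @param start starting tree (`phylo` with branch lengths over the
#'   alignment's taxa).
#' @param aln an [msa].
#' @param model a `subst_model`.
#' @param evaluator `"full"` or a `lasso_sample` trained on `aln`/`model`.
#' @param radius SPR rearrangement radius (default 5).
#' @param epsilon minimum log-likelihood improvement to accept a move
#'   (default 0.1).
#' @param top_k number of best lazily-scored neighbors to optimize at a stall
#'   (default 50).
#' @return list with `tree` (final, fully optimized branch lengths),
#'   `final_ll` (full-alignment log-likelihood), `trace` (accepted-move data
#'   frame with columns move, ll, mode, phase), `n_moves`, and `counters`
#'   (named evaluation counts: `full`, `approx`).
#' @export
greedy_spr_search <- function(start, aln, model, evaluator = "full",
                              radius = 5, epsilon = 0.1, top_k = 50) {
  counter <- new.env(parent = emptyenv())
  full_dat <- ll_data(aln, model)
  if (identical(evaluator, "full")) {
    res <- .spr_climb(start, full_dat, full_dat, radius, epsilon, top_k,
                      counter = counter, mode = "full")
    final_tree <- res$tree
    final_ll <- res$final_ll
  } else if (inherits(evaluator, "lasso_sample")) {
    adat <- sample_ll_data(aln, model, evaluator)
    b0 <- evaluator$intercept
    res <- .spr_climb(start, adat, adat, radius, epsilon, top_k,
                      scan_offset = b0, opt_offset = b0,
                      counter = counter, mode = "lasso")
    # final report on the full alignment
    final_tree <- optimize_branch_lengths(res$tree, full_dat,
                                          counter = counter)
    final_ll <- attr(final_tree, "loglik")
  } else stop("evaluator must be \"full\" or a lasso_sample", call. = FALSE)
  list(tree = final_tree, final_ll = final_ll, trace = res$trace,
       n_moves = res$n_moves,
       counters = list(full = counter$full %||% 0,
                       approx = counter$approx %||% 0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Two-phase Lasso SPR search
#'
#' Phase 1 is a Lasso-only greedy SPR search run to a local maximum.  Phase 2
#' restarts from its result: neighbor scans still use the Lasso approximation,
#' but branch-length optimization of the top-`top_k` candidates and acceptance
#' decisions use the full alignment.  The final log-likelihood is computed
#' with all sites.
#'
#' @inheritParams greedy_spr_search
#' @param sample a `lasso_sample` trained on `aln`/`model`.
#' @return as [greedy_spr_search()], plus `phase1_ll` (full-alignment
#'   log-likelihood of the phase-1 result) and a combined two-phase `trace`.
#' @export
two_phase_search <- function(start, aln, model, sample, radius = 5,
                             epsilon = 0.1, top_k = 50) {
  counter <- new.env(parent = emptyenv())
  full_dat <- ll_data(aln, model)
  adat <- sample_ll_data(aln, model, sample)
  b0 <- sample$intercept
  p1 <- .spr_climb(start, adat, adat, radius, epsilon, top_k,
                   scan_offset = b0, opt_offset = b0,
                   counter = counter, mode = "phase1")
  p1_full <- optimize_branch_lengths(p1$tree, full_dat, counter = counter)
  phase1_ll <- attr(p1_full, "loglik")
  p2 <- .spr_climb(p1_full, adat, full_dat, radius, epsilon, top_k,
                   scan_offset = b0, opt_offset = 0,
                   counter = counter, mode = "phase2")
  list(tree = p2$tree, final_ll = p2$final_ll, phase1_ll = phase1_ll,
       trace = rbind(p1$trace, p2$trace),
       n_moves = p1$n_moves + p2$n_moves,
       counters = list(full = counter$full %||% 0,
                       approx = counter$approx %||% 0))
}
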