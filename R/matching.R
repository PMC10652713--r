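# Case-control matching: eligibility screening and greedy age/gender
# matching of controls to patients, with an exhaustive optimal mode for
# small pools.

#' Control eligibility criteria
#'
#' A control is eligible when they report no chronic pain condition, acute
#' pain (NRS) at or below `max_nrs_now`, and BPI now / 24-hour-mean scores
#' below `max_bpi`. The default NRS cut-off is inclusive (`<= 3`);
#' `nrs_inclusive = FALSE` gives the strict `< 3` reading. `strict_mode`
#' additionally restricts both BPI items to {0, 1, 2}.
#'
#' @param require_no_chronic_pain Drop controls with a chronic pain flag.
#' @param max_nrs_now NRS cut-off (0-10).
#' @param nrs_inclusive Whether the NRS cut-off is `<=` (default) or `<`.
#' @param max_bpi Exclusive upper bound for `bpi_now` and `bpi_24h_mean`.
#' @param strict_mode Require BPI now and 24-hour mean in {0, 1, 2}.
#' @return An `eligibility_criteria` list.
#' @export
eligibility_criteria <- function(require_no_chronic_pain = TRUE,
                                 max_nrs_now = 3,
                                 nrs_inclusive = TRUE,
                                 max_bpi = 5,
                                 strict_mode = FALSE) {
  stopifnot(max_nrs_now >= 0, max_nrs_now <= 10, max_bpi >= 0, max_bpi <= 10)
  structure(list(require_no_chronic_pain = isTRUE(require_no_chronic_pain),
                 max_nrs_now = max_nrs_now,
                 nrs_inclusive = isTRUE(nrs_inclusive),
                 max_bpi = max_bpi,
                 strict_mode = isTRUE(strict_mode)),
            class = "eligibility_criteria")
}

#' Screen a control pool for matching eligibility
#'
#' @param pool Participant data frame (controls).
#' @param criteria An [eligibility_criteria()].
#' @return The eligible subset of `pool`.
#' @export
eligible_controls <- function(pool, criteria = eligibility_criteria()) {
  ok <- rep(TRUE, nrow(pool))
  if (criteria$require_no_chronic_pain) ok <- ok & !pool$chronic_pain_flag
  ok <- ok & if (criteria$nrs_inclusive) pool$nrs_now <= criteria$max_nrs_now
             else pool$nrs_now < criteria$max_nrs_now
  ok <- ok & pool$bpi_now < criteria$max_bpi &
    pool$bpi_24h_mean < criteria$max_bpi
  if (criteria$strict_mode)
    ok <- ok & pool$bpi_now %in% 0:2 & pool$bpi_24h_mean %in% 0:2
  pool[ok, , drop = FALSE]
}

#' Select age- and gender-matched controls
#'
#' Pairs each patient with an unused eligible control of the same gender so
#' that the age difference is the smallest possible, prioritising controls
#' with low current pain: exact age ties are broken by lowest `nrs_now`,
#' then lowest `bpi_24h_mean`, then a seeded uniform draw. Patients are
#' processed scarcest-first (fewest same-gender candidates first), greedily
#' and without replacement; patients with no remaining candidate are
#' reported unmatched.
#'
#' `method = "optimal"` instead minimises the total absolute age difference
#' over all one-to-one gender-respecting assignments (maximising the number
#' matched first). It is exhaustive and intended for small pools (at most
#' 10 patients and 16 eligible controls per gender).
#'
#' @param patients,pool Participant data frames.
#' @param criteria An [eligibility_criteria()] applied to `pool`.
#' @param seed Seed for the final tie-break draw.
#' @param method `"greedy"` (default) or `"optimal"`.
#' @return A `match_result`: `pairs` (patient_id, control_id, age_diff),
#'   `unmatched`, `criteria`, `seed`.
#' @export
match_controls <- function(patients, pool, criteria = eligibility_criteria(),
                           seed = 1L, method = c("greedy", "optimal")) {
  method <- match.arg(method)
  stopifnot(nrow(patients) > 0)
  elig <- eligible_controls(pool, criteria)
  if (nrow(elig) == 0L) warning("no eligible controls; all patients unmatched")
  res <- if (method == "greedy") match_greedy(patients, elig, seed)
         else match_optimal(patients, elig)
  structure(list(pairs = res$pairs, unmatched = res$unmatched,
                 criteria = criteria, seed = as.integer(seed),
                 method = method),
            class = "match_result")
}

match_greedy <- function(patients, elig, seed) {
  n_cand <- vapply(seq_len(nrow(patients)), function(i)
    sum(elig$gender == patients$gender[i]), integer(1))
  ord <- order(n_cand, patients$id)
  used <- rep(FALSE, nrow(elig))
  pairs <- vector("list", nrow(patients))
  unmatched <- character(0)
  with_seed(substream_seed(seed, "match"), {
    for (i in ord) {
      cand <- which(!used & elig$gender == patients$gender[i])
      if (length(cand) == 0L) {
        unmatched <- c(unmatched, patients$id[i])
        next
      }
      ad <- abs(elig$age[cand] - patients$age[i])
      cand <- cand[ad == min(ad)]
      if (length(cand) > 1L)
        cand <- cand[elig$nrs_now[cand] == min(elig$nrs_now[cand])]
      if (length(cand) > 1L)
        cand <- cand[elig$bpi_24h_mean[cand] == min(elig$bpi_24h_mean[cand])]
      pick <- if (length(cand) > 1L) cand[sample.int(length(cand), 1L)]
              else cand
      used[pick] <- TRUE
      pairs[[i]] <- data.frame(patient_id = patients$id[i],
                               control_id = elig$id[pick],
                               age_diff = abs(elig$age[pick] - patients$age[i]),
                               stringsAsFactors = FALSE)
    }
  })
  pairs <- do.call(rbind, pairs[!vapply(pairs, is.null, logical(1))])
  if (is.null(pairs))
    pairs <- data.frame(patient_id = character(0), control_id = character(0),
                        age_diff = numeric(0))
  list(pairs = pairs[order(pairs$patient_id), , drop = FALSE],
       unmatched = sort(unmatched))
}

# Exhaustive minimal-total-age-difference assignment (per gender stratum),
# maximising the number of matched patients first. Branch-and-bound over
# patients in order; memoised on (patient index, used-control bitmask).
match_optimal <- function(patients, elig) {
  pairs <- list(); unmatched <- character(0)
  for (g in unique(patients$gender)) {
    pi <- which(patients$gender == g)
    ci <- which(elig$gender == g)
    if (length(ci) == 0L) { unmatched <- c(unmatched, patients$id[pi]); next }
    if (length(pi) > 10L || length(ci) > 16L)
      stopf("optimal matching is exhaustive; stratum too large (%d patients, %d controls)",
            length(pi), length(ci))
    cost <- outer(patients$age[pi], elig$age[ci],
                  function(a, b) abs(a - b))
    sol <- solve_assignment(cost)
    for (k in seq_along(pi)) {
      j <- sol[k]
      if (is.na(j)) unmatched <- c(unmatched, patients$id[pi[k]])
      else pairs[[length(pairs) + 1L]] <-
          data.frame(patient_id = patients$id[pi[k]],
                     control_id = elig$id[ci[j]],
                     age_diff = cost[k, j], stringsAsFactors = FALSE)
    }
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs)
           else data.frame(patient_id = character(0),
                           control_id = character(0), age_diff = numeric(0))
  list(pairs = pairs[order(pairs$patient_id), , drop = FALSE],
       unmatched = sort(unmatched))
}

# Minimal-cost one-to-one assignment of rows (patients) to columns
# (controls); unassignable rows (no columns left) are skipped at a large
# penalty so matched count is maximised first. Returns column index per
# row (NA = unmatched).
solve_assignment <- function(cost) {
  nr <- nrow(cost); nc <- ncol(cost)
  skip_pen <- sum(cost) + 1e6
  memo <- new.env(hash = TRUE, parent = emptyenv())
  best <- function(i, used) {
    if (i > nr) return(list(cost = 0, pick = integer(0)))
    key <- paste(i, paste(used, collapse = ""))
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    # option: leave row i unmatched
    res <- best(i + 1L, used)
    out <- list(cost = res$cost + skip_pen, pick = c(NA_integer_, res$pick))
    for (j in which(!used)) {
      u2 <- used; u2[j] <- TRUE
      res <- best(i + 1L, u2)
      tot <- cost[i, j] + res$cost
      if (tot < out$cost) out <- list(cost = tot, pick = c(j, res$pick))
    }
    memo[[key]] <- out
    out
  }
  sol <- best(1L, rep(FALSE, nc))
  attr(sol$pick, "total_cost") <- sol$cost
  sol$pick
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("match_result (%s): %d matched, %d unmatched, mean |age diff| %.2f\n",
              x$method, nrow(x$pairs), length(x$unmatched),
              if (nrow(x$pairs)) mean(x$pairs$age_diff) else NA_real_))
  invisible(x)
}
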