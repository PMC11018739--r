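#' The study enrollment/exclusion ledger
#'
#' Ordered accounting of the cohort flow: participants enrolled, participants
#' removed by listwise deletion for missing data, eyes entering image
#' processing, and eyes excluded because their vasculature was not prominent
#' enough for template matching. `study_ledger()` returns the packaged
#' default flow; [replay_ledger()] replays any ledger into running totals.
#'
#' @return data.frame of class `cohort_ledger` with columns `stage_label`,
#'   `participants_delta`, `eyes_delta`, `reason`.
#' @export
study_ledger <- function() {
  structure(data.frame(
    stage_label = c("enrolled", "missing_data", "imaging_complete",
                    "registration_failure", "analyzed"),
    participants_delta = c(136L, -16L, 0L, 0L, 0L),
    eyes_delta = c(0L, 0L, 240L, -12L, 0L),
    reason = c("participants initially included",
               "listwise deletion, missing data",
               "eyes of included participants",
               "vasculature not prominent enough for template matching",
               "eyes entering analysis")),
    class = c("cohort_ledger", "data.frame"))
}

#' Replay a cohort ledger into running stage totals
#'
#' @param ledger a data.frame with `stage_label`, `participants_delta`,
#'   `eyes_delta` columns.
#' @return data.frame with per-stage running totals `participants`, `eyes`;
#'   errors if any running total goes negative.
#' @export
replay_ledger <- function(ledger) {
  stopifnot(is.data.frame(ledger),
            all(c("stage_label", "participants_delta", "eyes_delta") %in%
                  names(ledger)))
  if (nrow(ledger) == 0L)
    return(data.frame(stage_label = character(0), participants = integer(0),
                      eyes = integer(0)))
  p <- cumsum(ledger$participants_delta)
  e <- cumsum(ledger$eyes_delta)
  if (any(p < 0) || any(e < 0))
    stop("invalid ledger: running total goes negative", call. = FALSE)
  data.frame(stage_label = ledger$stage_label, participants = p, eyes = e)
}

#' Simulate the full synthetic cohort
#'
#' Generates all analyzed eyes nested within subjects: 33 control subjects
#' contribute 66 control eyes; 87 AMD subjects contribute 140 AMD eyes
#' (30 early/intermediate, 110 advanced) plus 22 lesion-free fellow eyes;
#' the remaining 12 fellow eyes are the ones the packaged ledger records as
#' registration-failure exclusions, reproducing the study flow (136 enrolled
#' minus 16 missing = 120 participants; 240 eyes minus 12 = 228 analyzed).
#' The subject/eye structure and the ledger are deterministic; sensitivity
#' draws and geometry flow from the master seed.
#'
#' @param config a [generator_config()]; group sizes may be scaled down for
#'   quick runs (the subject structure scales with them).
#' @param render whether to render per-eye image pairs.
#' @return list of class `synthetic_cohort`: `eyes` (list of bundles),
#'   `eye_table` (subject/eye metadata), `ledger`, `config`.
#' @export
simulate_cohort <- function(config = generator_config(), render = TRUE) {
  rs <- .Random.seed_save()
  on.exit(.Random.seed_restore(rs))
  set.seed(config$seed)
  n <- config$n_per_group
  n_ctrl_subj <- ceiling(n[["control"]] / 2)
  n_amd_eyes <- n[["early_intermediate"]] + n[["advanced"]]
  n_fellow <- n[["fellow"]]
  # unilateral AMD subjects = fellow eyes analyzed + fellow eyes excluded at
  # registration (12 of 22 in the reference flow)
  n_excluded <- round(n_fellow * 12 / 22)
  n_uni <- n_fellow + n_excluded
  if (n_amd_eyes < n_uni)
    stop("group sizes inconsistent: more unilateral subjects than AMD eyes",
         call. = FALSE)
  n_bil <- (n_amd_eyes - n_uni) %/% 2
  if (n_bil * 2 + n_uni != n_amd_eyes)
    n_uni <- n_amd_eyes - n_bil * 2  # absorb parity remainder
  rows <- list()
  subj <- 0L
  add_eye <- function(subj_id, laterality, group)
    data.frame(subject_id = sprintf("S%03d", subj_id), eye = laterality,
               group = group)
  ctrl_left <- n[["control"]]
  for (i in seq_len(n_ctrl_subj)) {
    subj <- subj + 1L
    rows[[length(rows) + 1L]] <- add_eye(subj, "OD", "control")
    ctrl_left <- ctrl_left - 1L
    if (ctrl_left > 0L) {
      rows[[length(rows) + 1L]] <- add_eye(subj, "OS", "control")
      ctrl_left <- ctrl_left - 1L
    }
  }
  amd_groups <- c(rep("early_intermediate", n[["early_intermediate"]]),
                  rep("advanced", n[["advanced"]]))
  gi <- 1L
  for (i in seq_len(n_bil)) {
    subj <- subj + 1L
    rows[[length(rows) + 1L]] <- add_eye(subj, "OD", amd_groups[gi]); gi <- gi + 1L
    rows[[length(rows) + 1L]] <- add_eye(subj, "OS", amd_groups[gi]); gi <- gi + 1L
  }
  for (i in seq_len(n_uni)) {
    subj <- subj + 1L
    rows[[length(rows) + 1L]] <- add_eye(subj, "OD", amd_groups[gi]); gi <- gi + 1L
    if (i <= n_fellow)  # the rest lose their fellow eye at registration
      rows[[length(rows) + 1L]] <- add_eye(subj, "OS", "fellow")
  }
  tab <- do.call(rbind, rows)
  eye_seeds <- sample.int(.Machine$integer.max, nrow(tab))
  subj_ids <- unique(tab$subject_id)
  z_subj <- stats::setNames(stats::rnorm(length(subj_ids)), subj_ids)
  eyes <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    eyes[[i]] <- simulate_eye(tab$group[i], config, eye_seeds[i],
                              z_subject = z_subj[[tab$subject_id[i]]],
                              render = render)
    tab$age[i] <- eyes[[i]]$age
    tab$sex[i] <- eyes[[i]]$sex
  }
  # subjects share one age/sex: take the first eye's draw
  for (s in unique(tab$subject_id)) {
    k <- which(tab$subject_id == s)
    tab$age[k] <- tab$age[k[1]]; tab$sex[k] <- tab$sex[k[1]]
    for (j in k) { eyes[[j]]$age <- tab$age[j]; eyes[[j]]$sex <- tab$sex[j] }
  }
  tab$eye_id <- paste0(tab$subject_id, "_", tab$eye)
  rownames(tab) <- NULL
  structure(list(eyes = eyes, eye_table = tab, ledger = study_ledger(),
                 config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d eyes / %d subjects (seed %d)\n",
              nrow(x$eye_table), length(unique(x$eye_table$subject_id)),
              x$config$seed))
  print(table(x$eye_table$group))
  invisible(x)
}
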