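#' Exclusion rules for the correlation analysis
#'
#' Global rules remove a case from every muscle's analysis: prior spine
#' surgery, and profound fatty atrophy defined on the paraspinal muscle
#' only (paraspinal fat% > `atrophy_threshold`). Per-muscle rules remove
#' listed case IDs from that muscle's analysis only (e.g. trapezius cases
#' with cropped or absent labels); by default they apply to both the raw
#' and adjusted cohorts.
#'
#' @param surgery apply the spine-surgery rule?
#' @param atrophy apply the paraspinal-atrophy rule?
#' @param atrophy_threshold paraspinal fat% above which a case counts as
#'   profound fatty atrophy (default 50).
#' @param per_muscle named list: muscle group -> case IDs to drop from
#'   that muscle's analysis.
#' @param per_muscle_in_raw apply per-muscle exclusions in the raw cohort
#'   too?
#' @return an `exclusion_rules` object.
#' @export
exclusion_rules <- function(surgery = TRUE, atrophy = TRUE,
                            atrophy_threshold = 50,
                            per_muscle = list(),
                            per_muscle_in_raw = TRUE) {
  bad <- setdiff(names(per_muscle), muscle_groups())
  if (length(bad)) stop("per_muscle names not muscle groups: ",
                        paste(bad, collapse = ", "))
  structure(list(surgery = isTRUE(surgery), atrophy = isTRUE(atrophy),
                 atrophy_threshold = atrophy_threshold,
                 per_muscle = per_muscle,
                 per_muscle_in_raw = isTRUE(per_muscle_in_raw)),
            class = "exclusion_rules")
}

.atrophy_flag <- function(cohort, rules) {
  if (!is.null(cohort$atrophy)) return(as.logical(cohort$atrophy))
  if (is.null(cohort$fat_paraspinal))
    stop("cohort has neither an atrophy flag nor a fat_paraspinal column")
  cohort$fat_paraspinal > rules$atrophy_threshold
}

#' Apply global confounder exclusions to a cohort
#'
#' Removes cases flagged for prior spine surgery or profound paraspinal
#' fatty atrophy. A case triggering both rules is excluded (and logged)
#' once, with both triggering rules recorded.
#'
#' @param cohort cohort data.frame (see [generate_cohort()] for the
#'   column contract).
#' @param rules an [exclusion_rules()].
#' @return list with `cohort` (retained rows) and `log` (data.frame
#'   case_id / rules, one row per excluded case).
#' @export
apply_exclusions <- function(cohort, rules = exclusion_rules()) {
  stopifnot(is.data.frame(cohort), inherits(rules, "exclusion_rules"))
  surg <- if (rules$surgery && !is.null(cohort$surgery))
    as.logical(cohort$surgery) else rep(FALSE, nrow(cohort))
  atr <- if (rules$atrophy) .atrophy_flag(cohort, rules)
         else rep(FALSE, nrow(cohort))
  drop <- surg | atr
  why <- character(sum(drop))
  if (any(drop)) {
    why <- apply(cbind(surgery = surg[drop], atrophy = atr[drop]), 1,
                 function(r) paste(names(r)[r], collapse = "+"))
  }
  log <- data.frame(case_id = cohort$case_id[drop], rules = why,
                    stringsAsFactors = FALSE)
  rownames(log) <- NULL
  list(cohort = cohort[!drop, , drop = FALSE], log = log)
}

#' Pearson correlation between Cobb angle and one muscle's fat%
#'
#' Sample Pearson r with a two-sided p-value from the t transform with
#' n - 2 degrees of freedom. No multiple-testing correction is applied
#' (the analysis is exploratory). Per-muscle exclusions from `rules` are
#' applied to this muscle before computing.
#'
#' @param cohort cohort data.frame.
#' @param muscle muscle group name.
#' @param outcome outcome column (default `"cobb_mean"`).
#' @param rules optional [exclusion_rules()] supplying per-muscle ID lists.
#' @return list with `r`, `p`, `n`.
#' @export
correlate <- function(cohort, muscle, outcome = "cobb_mean", rules = NULL) {
  col <- paste0("fat_", muscle)
  if (is.null(cohort[[col]])) stop("cohort has no column ", col)
  keep <- rep(TRUE, nrow(cohort))
  if (!is.null(rules) && length(rules$per_muscle[[muscle]]))
    keep <- !(cohort$case_id %in% rules$per_muscle[[muscle]])
  x <- cohort[[col]][keep]
  y <- cohort[[outcome]][keep]
  n <- length(x)
  if (n < 3L) return(list(r = NA_real_, p = NA_real_, n = n))
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in ", if (stats::sd(x) == 0) col else outcome)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  r <- max(-1, min(1, r))
  tt <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  list(r = r, p = p, n = n)
}

#' Raw and adjusted correlation tables for all muscles
#'
#' Reproduces the before/after-confounder-exclusion structure: the raw
#' cohort is the input as-is; the adjusted cohort has [apply_exclusions()]
#' applied. Per-muscle exclusions apply in both by default (configurable
#' via `rules$per_muscle_in_raw`).
#'
#' @param cohort cohort data.frame.
#' @param rules an [exclusion_rules()].
#' @param cohorts which cohort variants to compute.
#' @return data.frame with cohort_label, muscle, r, p_two_sided, n_used;
#'   the exclusion log is attached as attribute `exclusion_log`.
#' @export
run_table <- function(cohort, rules = exclusion_rules(),
                      cohorts = c("raw", "adjusted")) {
  cohorts <- match.arg(cohorts, several.ok = TRUE)
  adj <- NULL
  if ("adjusted" %in% cohorts) adj <- apply_exclusions(cohort, rules)
  rows <- list()
  for (lab in cohorts) {
    dat <- if (lab == "raw") cohort else adj$cohort
    r_rules <- if (lab == "adjusted" || rules$per_muscle_in_raw) rules else NULL
    for (g in muscle_groups()) {
      res <- correlate(dat, g, rules = r_rules)
      rows[[length(rows) + 1L]] <-
        data.frame(cohort_label = lab, muscle = g, r = res$r,
                   p_two_sided = res$p, n_used = res$n,
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(adj)) attr(out, "exclusion_log") <- adj$log
  out
}

#' Stratified correlation table
#'
#' Same per-muscle computation on subsets defined by a stratification
#' column (`sex` or any logical flag). Strata with fewer than 3 cases are
#' reported with NA (undefined), never an error.
#'
#' @param cohort cohort data.frame.
#' @param by stratification column name.
#' @param rules optional [exclusion_rules()] for per-muscle exclusions.
#' @param strata stratum values to report; defaults to `c("M","F")` for
#'   sex and `c(TRUE, FALSE)` for logical flags, so an absent stratum is
#'   still reported as undefined.
#' @return data.frame with cohort_label (`by=value`), muscle, r,
#'   p_two_sided, n_used.
#' @export
stratify <- function(cohort, by = "sex", rules = NULL, strata = NULL) {
  if (is.null(cohort[[by]])) stop("cohort has no column ", by)
  if (is.null(strata))
    strata <- if (is.logical(cohort[[by]])) c(TRUE, FALSE) else
      if (by == "sex") c("M", "F") else sort(unique(cohort[[by]]))
  rows <- list()
  for (s in strata) {
    sub <- cohort[cohort[[by]] %in% s, , drop = FALSE]
    for (g in muscle_groups()) {
      res <- if (nrow(sub) >= 3L) {
        tryCatch(correlate(sub, g, rules = rules),
                 error = function(e) list(r = NA_real_, p = NA_real_,
                                          n = nrow(sub)))
      } else list(r = NA_real_, p = NA_real_, n = nrow(sub))
      rows[[length(rows) + 1L]] <-
        data.frame(cohort_label = paste0(by, "=", s), muscle = g,
                   r = res$r, p_two_sided = res$p, n_used = res$n,
                   stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Sensitivity analysis: drop cases holding a flag
#'
#' Recomputes the per-muscle correlation table after removing cases with
#' the given flag (vertebral compression fracture or transitional
#' vertebra).
#'
#' @param cohort cohort data.frame.
#' @param drop_flag flag column to drop (`"fracture"` or
#'   `"transitional"`).
#' @param rules optional [exclusion_rules()].
#' @return data.frame as in [stratify()].
#' @export
sensitivity <- function(cohort, drop_flag = c("fracture", "transitional"),
                        rules = NULL) {
  drop_flag <- match.arg(drop_flag)
  if (is.null(cohort[[drop_flag]])) stop("cohort has no column ", drop_flag)
  sub <- cohort[!as.logical(cohort[[drop_flag]]), , drop = FALSE]
  rows <- lapply(muscle_groups(), function(g) {
    res <- correlate(sub, g, rules = rules)
    data.frame(cohort_label = paste0("drop_", drop_flag), muscle = g,
               r = res$r, p_two_sided = res$p, n_used = res$n,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-muscle fat% summary table
#'
#' @param cohort cohort data.frame with `fat_<group>` columns.
#' @return data.frame with muscle, mean, sd (sample SD) over the cohort.
#' @export
summarize_fat <- function(cohort) {
  rows <- lapply(muscle_groups(), function(g) {
    v <- cohort[[paste0("fat_", g)]]
    if (is.null(v)) return(NULL)
    data.frame(muscle = g, mean = mean(v), sd = stats::sd(v),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
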