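# Canonical longitudinal data model: a cohort is a list of patient records,
# each holding a dosing history, trough observations and one covariate
# panel per observation (covariates may vary between TDM occasions).

COV_COLS <- c("WT", "HCT", "RBC", "DBIL", "BUN", "CLCR", "ALB", "SEX",
              "CYP3A5", "COMED_CA", "COMED_PPI", "COMED_VORI")
EVENT_COLS <- c("ID", "TIME", "AMT", "DV", "MDV", "POD", COV_COLS)

# Evaluate expr with a private RNG stream, restoring the caller's state.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

#' Construct a patient record
#'
#' @param patient_id character id.
#' @param doses data frame `time` (h since first transplant-day dose),
#'   `amt` (mg, > 0), time-sorted.
#' @param obs data frame `time` (h), `conc` (ng/mL), `pod` (days),
#'   `occasion` (1, 2, ... TDM), `censored` (`"none"`, `"low"`, `"high"`).
#' @param covariates data frame with one row per observation, columns
#'   `WT, HCT, RBC, DBIL, BUN, CLCR, ALB, SEX, CYP3A5, COMED_CA, COMED_PPI,
#'   COMED_VORI`.
#' @return object of class `tac_patient`.
#' @export
tac_patient <- function(patient_id, doses, obs, covariates) {
  rec <- structure(list(patient_id = as.character(patient_id),
                        doses = as.data.frame(doses),
                        obs = as.data.frame(obs),
                        covariates = as.data.frame(covariates)),
                   class = "tac_patient")
  validate_patient(rec)
  rec
}

validate_patient <- function(rec) {
  id <- rec$patient_id
  d <- rec$doses; o <- rec$obs; cv <- rec$covariates
  if (nrow(d) < 1) stop("patient ", id, ": no doses")
  if (any(d$amt <= 0)) stop("patient ", id, ": non-positive dose amount")
  if (any(d$time < 0)) stop("patient ", id, ": negative dose time")
  if (is.unsorted(d$time)) stop("patient ", id, ": doses not time-sorted")
  if (nrow(o)) {
    if (is.unsorted(o$time)) stop("patient ", id, ": observations not time-sorted")
    if (any(o$time < d$time[1]))
      stop("validation error: patient ", id,
           " has an observation before the first dose")
    if (!all(o$occasion == seq_len(nrow(o))))
      stop("patient ", id, ": occasion index not consecutive")
    if (nrow(cv) != nrow(o))
      stop("patient ", id, ": need one covariate panel per observation")
    if (!all(COV_COLS %in% names(cv)))
      stop("patient ", id, ": covariate panel lacks column(s) ",
           paste(setdiff(COV_COLS, names(cv)), collapse = ", "))
    ok <- is.na(cv$CYP3A5) | cv$CYP3A5 %in% c(0, 1, 2)
    if (!all(ok)) stop("patient ", id, ": CYP3A5 code outside {0,1,2}")
    if (any(cv$HCT <= 0 | cv$HCT >= 1, na.rm = TRUE))
      stop("patient ", id, ": HCT must be a fraction in (0,1)")
  }
  invisible(rec)
}

#' @export
print.tac_patient <- function(x, ...) {
  cat(sprintf("<tac_patient %s: %d doses, %d troughs (%d censored)>\n",
              x$patient_id, nrow(x$doses), nrow(x$obs),
              sum(x$obs$censored != "none")))
  invisible(x)
}

as_cohort <- function(records) {
  structure(records, class = "tac_cohort")
}

#' @export
print.tac_cohort <- function(x, ...) {
  no <- sum(vapply(x, function(r) nrow(r$obs), 0L))
  nc <- sum(vapply(x, function(r) sum(r$obs$censored != "none"), 0L))
  cat(sprintf("<tac_cohort: %d patients, %d troughs (%d censored)>\n",
              length(x), no, nc))
  invisible(x)
}

#' @export
`[.tac_cohort` <- function(x, i) as_cohort(unclass(x)[i])

#' Read a NONMEM-style event table
#'
#' Parses a comma-separated event table with one row per dose or trough
#' observation.  Dose rows have `AMT > 0` and `MDV = 1` (empty `DV`);
#' observation rows have `MDV = 0` and a `DV` value with one covariate
#' snapshot on the same row.  Observations with `DV` outside the assay
#' range are loaded and flagged censored (`"low"`/`"high"`), never dropped.
#'
#' @param path CSV path.
#' @param dialect list of options; `assay_range` (default `c(2, 50)` ng/mL).
#' @return a `tac_cohort` (list of [tac_patient()] records, grouped by `ID`,
#'   events time-sorted).
#' @export
read_event_table <- function(path, dialect = list()) {
  assay <- dialect$assay_range %||% c(2, 50)
  df <- read.csv(path, stringsAsFactors = FALSE)
  mandatory <- c("ID", "TIME", "AMT", "DV", "MDV")
  miss <- setdiff(mandatory, names(df))
  if (length(miss))
    stop("schema error: missing mandatory column(s): ",
         paste(miss, collapse = ", "))
  covs_present <- intersect(COV_COLS, names(df))
  recs <- lapply(split(df, factor(df$ID, levels = unique(df$ID))), function(g) {
    g <- g[order(g$TIME, !is.na(g$AMT) & g$AMT > 0), , drop = FALSE]
    is_dose <- !is.na(g$MDV) & g$MDV == 1 & !is.na(g$AMT) & g$AMT > 0
    is_obs <- !is.na(g$MDV) & g$MDV == 0
    doses <- data.frame(time = g$TIME[is_dose], amt = g$AMT[is_dose])
    dv <- g$DV[is_obs]
    cens <- ifelse(is.na(dv), "none",
                   ifelse(dv < assay[1], "low",
                          ifelse(dv > assay[2], "high", "none")))
    obs <- data.frame(time = g$TIME[is_obs], conc = dv,
                      pod = if ("POD" %in% names(g)) g$POD[is_obs]
                            else g$TIME[is_obs] / 24,
                      occasion = seq_len(sum(is_obs)),
                      censored = cens, stringsAsFactors = FALSE)
    cv <- g[is_obs, covs_present, drop = FALSE]
    for (nm in setdiff(COV_COLS, covs_present)) cv[[nm]] <- NA_real_
    rownames(cv) <- NULL
    tac_patient(g$ID[1], doses, obs, cv[, COV_COLS, drop = FALSE])
  })
  names(recs) <- NULL
  as_cohort(recs)
}

#' Write a cohort as a NONMEM-style event table
#'
#' Inverse of [read_event_table()]: dose rows carry `MDV = 1` and
#' last-observation-carried-forward covariates (backward-filled before the
#' first trough); observation rows carry `MDV = 0`, the measured `DV` and
#' that occasion's covariate panel.  `read_event_table(write_event_table(x))`
#' reproduces `x` field for field.
#'
#' @param records a `tac_cohort` or list of [tac_patient()] records.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_event_table <- function(records, path) {
  if (!length(records)) {
    hdr <- as.data.frame(setNames(rep(list(numeric(0)), length(EVENT_COLS)),
                                  EVENT_COLS))
    ok <- tryCatch({ write.csv(hdr, path, row.names = FALSE, na = ""); TRUE },
                   error = function(e) e)
    if (!isTRUE(ok)) stop("I/O error writing ", path, ": ",
                          conditionMessage(ok))
    return(invisible(path))
  }
  rows <- lapply(records, function(r) {
    no <- nrow(r$obs)
    ocv <- r$covariates
    # LOCF panel index for each dose: last observation at or before the dose,
    # backward-filled with the first panel for doses preceding every trough
    if (no) {
      di <- findInterval(r$doses$time, r$obs$time)
      di[di == 0] <- 1
      dcv <- ocv[di, , drop = FALSE]
      dpod <- r$obs$pod[di]
    } else {
      dcv <- ocv[rep(NA_integer_, nrow(r$doses)), , drop = FALSE]
      dpod <- rep(NA_real_, nrow(r$doses))
    }
    dose_rows <- cbind(data.frame(ID = r$patient_id, TIME = r$doses$time,
                                  AMT = r$doses$amt, DV = NA_real_, MDV = 1,
                                  POD = dpod),
                       dcv)
    obs_rows <- cbind(data.frame(ID = r$patient_id, TIME = r$obs$time,
                                 AMT = NA_real_, DV = r$obs$conc, MDV = 0,
                                 POD = r$obs$pod),
                      ocv)
    out <- rbind(dose_rows, obs_rows)
    out[order(out$TIME, out$MDV == 1), , drop = FALSE]
  })
  df <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(df)) {
    df <- as.data.frame(setNames(rep(list(numeric(0)), length(EVENT_COLS)),
                                 EVENT_COLS))
  }
  ok <- tryCatch({ write.csv(df, path, row.names = FALSE, na = ""); TRUE },
                 error = function(e) e)
  if (!isTRUE(ok)) stop("I/O error writing ", path, ": ",
                        conditionMessage(ok))
  invisible(path)
}

#' Split a cohort into training and test sets by patient
#'
#' The split is by patient, never by observation, so no patient contributes
#' to both sets; the training fraction matches `fraction` to within one
#' patient and the partition is deterministic for a fixed seed.
#'
#' @param records a `tac_cohort`.
#' @param fraction training fraction in (0, 1); default 0.8.
#' @param seed integer seed.
#' @return list with `tac_cohort` elements `train` and `test`.
#' @export
split_train_test <- function(records, fraction = 0.8, seed = 1) {
  if (!(is.numeric(fraction) && length(fraction) == 1 &&
        fraction > 0 && fraction < 1))
    stop("fraction must be a single number in (0, 1)")
  n <- length(records)
  if (n < 5) stop("need at least 5 patients to split")
  n_train <- max(1L, min(n - 1L, as.integer(round(fraction * n))))
  idx <- with_seed(seed, sample.int(n, n_train))
  list(train = as_cohort(unclass(records)[sort(idx)]),
       test = as_cohort(unclass(records)[sort(setdiff(seq_len(n), idx))]))
}
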