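#' Edit calf birth-weight records
#'
#' Applies the standard edits before genetic analysis, in order:
#' \enumerate{
#'   \item records with a missing mandatory field are rejected;
#'   \item birth weights strictly above 60 kg or strictly below 20 kg are
#'     excluded (the boundaries 20 and 60 are retained);
#'   \item gestation lengths outside 260-300 d are excluded (the
#'     gestation-length classes cover only that range);
#'   \item only dams with at least `min_offspring` remaining calves, each
#'     from a distinct parity, are kept (repeated records per dam are what
#'     identifies the maternal permanent-environmental component).
#' }
#' The dam rule is applied after the record-level rules and re-applied until
#' stable, so editing is idempotent.
#'
#' @param records data.frame with columns `calf_id`, `dam_id`, `sire_id`,
#'   `herd_id`, `birth_date`, `sex`, `birth_type`, `biw_kg`,
#'   `gestation_len_d`, `dam_parity`.
#' @param biw_range Retained birth-weight range in kg (inclusive).
#' @param gl_range Retained gestation-length range in days (inclusive).
#' @param min_offspring Minimum number of retained calves per dam, each from
#'   a distinct parity.
#' @return A list with `records` (the retained rows) and `log`, a data.frame
#'   of per-rule exclusion counts (`rule`, `n_dropped`).
#' @export
edit_phenotypes <- function(records, biw_range = c(20, 60),
                            gl_range = c(260, 300), min_offspring = 3L) {
  mandatory <- c("calf_id", "dam_id", "sire_id", "herd_id", "birth_date",
                 "sex", "birth_type", "biw_kg", "gestation_len_d",
                 "dam_parity")
  missing_cols <- setdiff(mandatory, names(records))
  if (length(missing_cols)) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  }
  n0 <- nrow(records)
  incomplete <- !stats::complete.cases(records[mandatory])
  records <- records[!incomplete, , drop = FALSE]
  n_missing <- sum(incomplete)

  out_biw <- records$biw_kg < biw_range[1] | records$biw_kg > biw_range[2]
  records <- records[!out_biw, , drop = FALSE]

  out_gl <- records$gestation_len_d < gl_range[1] |
    records$gestation_len_d > gl_range[2]
  records <- records[!out_gl, , drop = FALSE]

  # dams need >= min_offspring retained calves from distinct parities;
  # iterate to a fixed point (dropping one dam cannot re-qualify another,
  # so a single pass suffices, but the loop documents idempotence)
  n_dam_rule <- 0L
  repeat {
    n_par <- tapply(records$dam_parity, records$dam_id,
                    function(p) length(unique(p)))
    bad_dams <- names(n_par)[n_par < min_offspring]
    drop <- records$dam_id %in% bad_dams
    if (!any(drop)) break
    n_dam_rule <- n_dam_rule + sum(drop)
    records <- records[!drop, , drop = FALSE]
    if (!nrow(records)) break
  }

  log <- data.frame(
    rule = c("missing_field", "biw_out_of_range", "gestation_out_of_range",
             "dam_offspring_parity"),
    n_dropped = c(n_missing, sum(out_biw), sum(out_gl), n_dam_rule),
    stringsAsFactors = FALSE
  )
  stopifnot(n0 - sum(log$n_dropped) == nrow(records))
  rownames(records) <- NULL
  list(records = records, log = log)
}

#' Fixed-effect classes for the birth-weight models
#'
#' Maps each edited record onto the model factors: herd-birth-year (`hy`),
#' herd-birth-year-month (`hym`), sex-by-birth-type (`sex_bt`, 4 classes),
#' gestation-length class (`gl_class`, inclusive bins 260-269, 270-274,
#' 275-279, 280-284, 285-289, 290-300 d) and dam parity class
#' (`parity_class`, parities 1-6 kept, everything above pooled into class 7).
#'
#' @param records Edited records (see [edit_phenotypes()]).
#' @return `records` with factor columns `hy`, `hym`, `sex_bt`, `gl_class`,
#'   `parity_class` appended.
#' @export
assign_classes <- function(records) {
  gl <- records$gestation_len_d
  gl_class <- rep(NA_integer_, length(gl))
  gl_class[gl >= 260 & gl <= 269] <- 1L
  gl_class[gl >= 270 & gl <= 274] <- 2L
  gl_class[gl >= 275 & gl <= 279] <- 3L
  gl_class[gl >= 280 & gl <= 284] <- 4L
  gl_class[gl >= 285 & gl <= 289] <- 5L
  gl_class[gl >= 290 & gl <= 300] <- 6L
  if (anyNA(gl_class)) {
    stop("gestation length outside class range 260-300 d for record(s): ",
         paste(utils::head(records$calf_id[is.na(gl_class)], 5L),
               collapse = ", "))
  }
  if (!all(records$sex %in% c("male", "female"))) {
    stop("sex must be 'male' or 'female'")
  }
  if (!all(records$birth_type %in% c("singleton", "twin"))) {
    stop("birth_type must be 'singleton' or 'twin'")
  }
  bd <- as.Date(records$birth_date)
  yr <- format(bd, "%Y")
  mo <- format(bd, "%m")
  records$hy <- factor(paste(records$herd_id, yr, sep = "_"))
  records$hym <- factor(paste(records$herd_id, yr, mo, sep = "_"))
  records$sex_bt <- factor(paste(records$sex, records$birth_type, sep = "_"),
                           levels = c("female_singleton", "female_twin",
                                      "male_singleton", "male_twin"))
  records$gl_class <- factor(gl_class, levels = 1:6)
  records$parity_class <- factor(pmin(as.integer(records$dam_parity), 7L),
                                 levels = 1:7)
  records
}
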