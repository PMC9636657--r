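#' @keywords internal
"_PACKAGE"

# Finite design space: 8 PGR treatments x 4 explants x 3 MS strengths x
# 2 sampling days = 192 culture conditions.

.explants <- c("leaf", "nodal", "root", "shoot")
.ms_levels <- c(1, 4, 8)
.sampling_days <- c(8, 25)

#' Plant growth regulator treatments
#'
#' The eight PGR treatments of the factorial design, as concentrations (mg/l)
#' of the two auxins (2,4-D, NAA) and two cytokinins (BAP, kinetin). The table
#' ships with the package as a plain CSV
#' (`system.file("extdata", "pgr_treatments.csv", package = "callusopt")`).
#' Treatment 8 is the hormone-free control.
#'
#' @return A data frame with columns `treatment_id`, `conc_24d`, `conc_bap`,
#'   `conc_kin`, `conc_naa`.
#' @export
#' @examples
#' pgr_treatments()
pgr_treatments <- function() {
  path <- system.file("extdata", "pgr_treatments.csv", package = "callusopt")
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(nrow(tab) == 8L, !anyDuplicated(tab$treatment_id))
  tab
}

#' Explant types of the design space
#' @return Character vector of the four explant types.
#' @export
explant_levels <- function() .explants

#' MS-medium strength multipliers of the design space
#' @return Numeric vector `c(1, 4, 8)`.
#' @export
ms_levels <- function() .ms_levels

#' Sampling days of the design space
#' @return Numeric vector `c(8, 25)`.
#' @export
sampling_days <- function() .sampling_days

#' Enumerate the full 192-condition design grid
#'
#' Expands every combination of treatment, explant, MS strength and sampling
#' day. Row order is fixed (treatment varies fastest, then explant, MS level,
#' day); functions that break ties between equally good conditions do so by
#' taking the first row in this order.
#'
#' @return A data frame with 192 rows and columns `treatment_id`, `explant`,
#'   `ms_level`, `sampling_day`.
#' @export
design_grid <- function() {
  g <- expand.grid(
    treatment_id = 1:8,
    explant = .explants,
    ms_level = .ms_levels,
    sampling_day = .sampling_days,
    KEEP.OUT.ATTRS = FALSE,
    stringsAsFactors = FALSE
  )
  g
}

.check_conditions <- function(conditions) {
  need <- c("treatment_id", "explant", "ms_level", "sampling_day")
  miss <- setdiff(need, names(conditions))
  if (length(miss) > 0) {
    stop("condition table is missing column(s): ", paste(miss, collapse = ", "))
  }
  bad_field <- function(ok, field) {
    if (any(!ok)) {
      stop(sprintf("invalid %s in row(s) %s", field,
                   paste(utils::head(which(!ok), 5), collapse = ", ")))
    }
  }
  bad_field(conditions$treatment_id %in% 1:8, "treatment_id")
  bad_field(conditions$explant %in% .explants, "explant")
  bad_field(conditions$ms_level %in% .ms_levels, "ms_level")
  bad_field(conditions$sampling_day %in% .sampling_days, "sampling_day")
  invisible(conditions)
}

#' Encode culture conditions as numeric feature vectors
#'
#' Maps each condition to the 10-dimensional feature layout used by the
#' surrogate models: the four PGR concentrations looked up from the treatment
#' table, the MS multiplier and sampling day kept numeric, and the explant as
#' a one-hot block (leaf, nodal, root, shoot). Explants are one-hot rather
#' than ordinal because they are unordered categories.
#'
#' @param conditions Data frame with columns `treatment_id`, `explant`,
#'   `ms_level`, `sampling_day` (one row per condition).
#' @param treatments Treatment lookup table, by default [pgr_treatments()].
#' @return Numeric matrix with one row per condition and columns `conc_24d`,
#'   `conc_bap`, `conc_kin`, `conc_naa`, `ms_level`, `sampling_day`,
#'   `explant_leaf`, `explant_nodal`, `explant_root`, `explant_shoot`.
#' @export
#' @examples
#' encode_conditions(data.frame(treatment_id = 6, explant = "shoot",
#'                              ms_level = 1, sampling_day = 8))
encode_conditions <- function(conditions, treatments = pgr_treatments()) {
  .check_conditions(conditions)
  idx <- match(conditions$treatment_id, treatments$treatment_id)
  if (anyNA(idx)) {
    stop("unknown treatment id(s): ",
         paste(unique(conditions$treatment_id[is.na(idx)]), collapse = ", "))
  }
  onehot <- outer(conditions$explant, .explants, "==") * 1
  x <- cbind(
    conc_24d = treatments$conc_24d[idx],
    conc_bap = treatments$conc_bap[idx],
    conc_kin = treatments$conc_kin[idx],
    conc_naa = treatments$conc_naa[idx],
    ms_level = conditions$ms_level,
    sampling_day = conditions$sampling_day,
    onehot
  )
  colnames(x)[7:10] <- paste0("explant_", .explants)
  x
}

#' Decode feature vectors back to culture conditions
#'
#' Inverse of [encode_conditions()] on the 192-point grid: the PGR
#' concentration quadruple is matched back to its treatment id and the one-hot
#' block to its explant.
#'
#' @param x Numeric matrix (or single vector) in the 10-column feature layout.
#' @param treatments Treatment lookup table.
#' @return Data frame of conditions.
#' @export
decode_features <- function(x, treatments = pgr_treatments()) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != 10) stop("feature matrix must have 10 columns")
  key <- function(m) apply(m, 1, paste, collapse = "|")
  conc <- as.matrix(treatments[, c("conc_24d", "conc_bap", "conc_kin", "conc_naa")])
  tid <- treatments$treatment_id[match(key(x[, 1:4, drop = FALSE]), key(conc))]
  if (anyNA(tid)) stop("PGR concentrations do not match any treatment")
  onehot <- x[, 7:10, drop = FALSE]
  if (any(abs(rowSums(onehot) - 1) > 1e-9) || any(onehot < 0)) {
    stop("explant indicators are not one-hot")
  }
  data.frame(
    treatment_id = tid,
    explant = .explants[max.col(onehot)],
    ms_level = x[, 5],
    sampling_day = x[, 6],
    stringsAsFactors = FALSE
  )
}

#' Speed of callus induction
#'
#' Derived rate relating the sampling day to the mean callus diameter. The
#' default `"as_written"` mode is sampling day divided by mean diameter
#' (day/mm), under which larger calli score *lower*; the `"inverted"` mode is
#' mean diameter divided by sampling day (mm/day), the physically conventional
#' growth rate that the optimizer maximizes as a speed desirability. Conditions
#' without callus (zero diameter) have speed 0 in both modes so that fully
#' failed conditions carry a well-defined outcome.
#'
#' @param sampling_day Sampling time in days (> 0). Vectorized.
#' @param mean_diameter Mean callus diameter in mm (>= 0). Vectorized.
#' @param mode `"as_written"` (day/diameter) or `"inverted"` (diameter/day).
#' @return Numeric speed values, 0 wherever `mean_diameter` is 0.
#' @export
#' @examples
#' compute_speed(8, 4)                     # 2 day/mm
#' compute_speed(8, 4, mode = "inverted")  # 0.5 mm/day
compute_speed <- function(sampling_day, mean_diameter,
                          mode = c("as_written", "inverted")) {
  mode <- match.arg(mode)
  if (any(sampling_day <= 0)) stop("sampling_day must be positive")
  if (any(mean_diameter < 0)) stop("mean_diameter must be non-negative")
  out <- if (mode == "as_written") {
    ifelse(mean_diameter > 0, sampling_day / mean_diameter, 0)
  } else {
    mean_diameter / sampling_day
  }
  as.numeric(out)
}

#' Summarize replicate records per culture condition
#'
#' Collapses replicate-level presence/absence and diameter data to one row per
#' condition: the induction percentage (0-100), the mean diameter over
#' *callused* replicates only (0 if none callused), and the induction speed
#' via [compute_speed()].
#'
#' @param records Replicate data frame as returned by [simulate_experiment()]
#'   or [read_replicates()].
#' @param speed_mode Passed to [compute_speed()].
#' @return Data frame with columns `treatment_id`, `explant`, `ms_level`,
#'   `sampling_day`, `n`, `induction_pct`, `mean_diameter_mm`, `speed`, one
#'   row per condition present in `records`.
#' @export
condition_summaries <- function(records, speed_mode = c("as_written", "inverted")) {
  speed_mode <- match.arg(speed_mode)
  cols <- c("treatment_id", "explant", "ms_level", "sampling_day")
  if (nrow(records) == 0) {
    out <- design_grid()[0, ]
    out$n <- integer(0)
    out$induction_pct <- numeric(0)
    out$mean_diameter_mm <- numeric(0)
    out$speed <- numeric(0)
    return(out)
  }
  .check_conditions(records)
  key <- interaction(records[cols], drop = TRUE, lex.order = TRUE)
  first <- !duplicated(key)
  out <- records[first, cols, drop = FALSE]
  n <- as.vector(tapply(records$callus, key, length))
  hits <- as.vector(tapply(records$callus, key, sum))
  dsum <- as.vector(tapply(records$diameter_mm * records$callus, key, sum))
  ord <- match(key[first], levels(key))
  out$n <- n[ord]
  out$induction_pct <- 100 * hits[ord] / n[ord]
  out$mean_diameter_mm <- ifelse(hits[ord] > 0, dsum[ord] / hits[ord], 0)
  out$speed <- compute_speed(out$sampling_day, out$mean_diameter_mm, speed_mode)
  rownames(out) <- NULL
  out
}

#' Read a replicate-level CSV
#'
#' Reads the canonical raw-data dialect (comma-separated, header row) with
#' columns `treatment_id, explant, ms_level, sampling_day, subset_id,
#' replicate_id, callus, diameter_mm` and validates every row against the
#' design space. An optional `columns` map renames user columns onto the
#' canonical schema, so differently labelled exports can be ingested without
#' editing the file.
#'
#' @param path Path to the CSV file.
#' @param columns Optional named character vector mapping canonical names to
#'   the file's column names, e.g. `c(diameter_mm = "diam")`.
#' @return Validated replicate data frame with `callus` as logical.
#' @export
read_replicates <- function(path, columns = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(columns)) {
    for (canon in names(columns)) {
      if (!columns[[canon]] %in% names(df)) {
        stop("mapped column not found in file: ", columns[[canon]])
      }
      names(df)[names(df) == columns[[canon]]] <- canon
    }
  }
  need <- c("treatment_id", "explant", "ms_level", "sampling_day",
            "subset_id", "replicate_id", "callus", "diameter_mm")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) stop("missing column(s): ", paste(miss, collapse = ", "))
  df <- df[, need]
  .check_conditions(df)
  df$callus <- as.logical(df$callus)
  if (anyNA(df$callus)) stop("callus column must be 0/1 or logical")
  if (anyNA(df$diameter_mm) || any(df$diameter_mm < 0)) {
    stop("diameter_mm must be present and non-negative in every row")
  }
  if (any(df$callus & df$diameter_mm == 0)) {
    warning("callused replicates with zero diameter present")
  }
  if (any(!df$callus & df$diameter_mm != 0)) {
    stop("non-callused replicates must have diameter_mm = 0 (rows ",
         paste(utils::head(which(!df$callus & df$diameter_mm != 0), 5),
               collapse = ", "), ")")
  }
  df
}

#' Write a replicate-level CSV
#'
#' @param records Replicate data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_replicates <- function(records, path) {
  out <- records
  out$callus <- as.integer(out$callus)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
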