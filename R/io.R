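#' @name table-schemas
#' @title CSV table schemas used throughout the pipeline
#'
#' @description
#' Every table exchanged between pipeline stages is a plain CSV with a header
#' row matching one of four declared schemas:
#' \describe{
#'   \item{binding_curve}{\code{ligand_id, tcr_conc_uM, response_RU,
#'     replicate_id} — one steady-state SPR titration point per row.}
#'   \item{antibody_trace}{\code{ligand_id, time_s, response_RU} — the
#'     conformation-sensitive antibody (W6/32) binding trace per ligand
#'     surface.}
#'   \item{dose_response}{\code{experiment_id, ligand_id, dose,
#'     response_percent} — ligand titrations with percent activation.}
#'   \item{potency_table}{\code{study_id, experiment_id, ligand_id}, an
#'     affinity column (\code{kd_uM} and/or \code{koff_per_s}),
#'     \code{potency}, \code{readout}, and an optional \code{flag} column
#'     (\code{"unreachable"}, \code{"extrapolated"}, ...).}
#' }
#' Units are fixed by convention: uM for concentrations and KD, s^-1 for
#' rates, RU for SPR response, percent for activation.
NULL

.schemas <- list(
  binding_curve = list(
    required = c("ligand_id", "tcr_conc_uM", "response_RU"),
    optional = "replicate_id",
    numeric = c("tcr_conc_uM", "response_RU")
  ),
  antibody_trace = list(
    required = c("ligand_id", "time_s", "response_RU"),
    optional = character(),
    numeric = c("time_s", "response_RU")
  ),
  dose_response = list(
    required = c("experiment_id", "ligand_id", "dose", "response_percent"),
    optional = character(),
    numeric = c("dose", "response_percent")
  ),
  potency_table = list(
    required = c("study_id", "experiment_id", "ligand_id", "potency"),
    optional = c("kd_uM", "koff_per_s", "readout", "flag"),
    numeric = c("potency", "kd_uM", "koff_per_s")
  )
)

#' Read and validate a pipeline CSV table
#'
#' Reads a CSV whose header must match one of the declared schemas (see
#' \link{table-schemas}). Numeric columns must parse as numbers; rows with a
#' missing required cell are rejected with their row index. A potency table
#' must carry at least one affinity column (\code{kd_uM} or
#' \code{koff_per_s}); rows flagged in a \code{flag} column may leave
#' \code{potency} empty.
#'
#' @param path Path to a CSV file.
#' @param schema One of \code{"binding_curve"}, \code{"antibody_trace"},
#'   \code{"dose_response"}, \code{"potency_table"}.
#' @return A data.frame of validated records.
#' @export
read_table <- function(path, schema) {
  if (!schema %in% names(.schemas)) {
    stop("unknown schema: ", schema)
  }
  if (!file.exists(path)) stop("file not found: ", path)
  sch <- .schemas[[schema]]
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE)
  if (nrow(df) == 0L) stop("empty table: ", path)
  missing_cols <- setdiff(sch$required, names(df))
  if (length(missing_cols)) {
    stop("schema '", schema, "': missing column(s) ",
         paste(missing_cols, collapse = ", "))
  }
  if (schema == "potency_table" &&
      !any(c("kd_uM", "koff_per_s") %in% names(df))) {
    stop("potency_table requires an affinity column (kd_uM or koff_per_s)")
  }
  keep <- intersect(names(df), c(sch$required, sch$optional))
  df <- df[, keep, drop = FALSE]
  flagged <- if ("flag" %in% names(df)) nzchar(df$flag) & !is.na(df$flag)
             else rep(FALSE, nrow(df))
  for (col in intersect(sch$numeric, names(df))) {
    raw <- df[[col]]
    val <- suppressWarnings(as.numeric(raw))
    empty <- is.na(raw) | raw == "" | raw == "NA"
    bad <- !empty & is.na(val)
    if (any(bad)) {
      stop("schema '", schema, "', column '", col, "': non-numeric cell in row ",
           which(bad)[1])
    }
    required_here <- col %in% sch$required && !(col == "potency")
    check_missing <- if (col == "potency") empty & !flagged else
      if (required_here) empty else rep(FALSE, nrow(df))
    if (any(check_missing)) {
      stop("schema '", schema, "', column '", col, "': missing value in row ",
           which(check_missing)[1])
    }
    df[[col]] <- val
  }
  df
}

#' Write a pipeline CSV table
#'
#' Plain CSV with header row, no quoting of numbers, no row names; the exact
#' inverse of \code{\link{read_table}} (round-trips preserve decimal text for
#' values written with full precision).
#'
#' @param df Data.frame to write.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_table <- function(df, path) {
  out <- df
  for (col in names(out)) {
    if (is.numeric(out[[col]])) {
      # shortest decimal text that parses back to the identical double
      txt <- vapply(out[[col]], function(x) {
        if (is.na(x)) return("")
        for (d in 1:17) {
          s <- sprintf("%.*g", d, x)
          if (as.numeric(s) == x) return(s)
        }
        sprintf("%.17g", x)
      }, character(1))
      out[[col]] <- txt
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
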