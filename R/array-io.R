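#' @importFrom utils read.delim read.csv write.csv
NULL

GPR_COLUMNS <- c("Block", "Row", "Column", "ID", "Name",
                 "F532 Median", "B532 Median", "F635 Median", "B635 Median",
                 "Flags", "SpotClass")

REQUIRED_SPOT_COLUMNS <- c("ID", "F532 Median", "B532 Median",
                           "F635 Median", "B635 Median", "Flags")

#' Read a GenePix-style spot table
#'
#' Reads one tab-delimited spot table (one file per array). The treated sample
#' is always the Cy3/532 channel and the control the Cy5/635 channel, so
#' `F532 Median` maps to the treated foreground and `F635 Median` to the
#' control foreground. GenePix flag convention: negative `Flags` values mean a
#' bad spot. A `SpotClass` column, when absent, defaults to `"experimental"`.
#'
#' @param path file path.
#' @param array_id identifier recorded for every row; defaults to the file
#'   name without extension.
#' @return data.frame with columns `array_id`, `probe_id`, `spot_class`,
#'   `f_treat`, `b_treat`, `f_ctrl`, `b_ctrl`, `flag`; any unrecognised input
#'   columns are preserved with their original names.
#' @export
read_spot_table <- function(path, array_id = NULL) {
  if (!file.exists(path))
    stop("spot table not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  missing_cols <- setdiff(REQUIRED_SPOT_COLUMNS, names(raw))
  if (length(missing_cols))
    stop("spot table ", path, " missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  intens <- c("F532 Median", "B532 Median", "F635 Median", "B635 Median")
  for (cl in intens) raw[[cl]] <- as.numeric(raw[[cl]])
  neg <- which(Reduce(`|`, lapply(raw[intens], function(x) !is.na(x) & x < 0)))
  if (length(neg))
    stop("spot table ", path, ": negative intensities in row(s) ",
         paste(utils::head(neg, 10), collapse = ", "), call. = FALSE)
  if (is.null(array_id))
    array_id <- sub("\\.[^.]*$", "", basename(path))
  out <- data.frame(
    array_id = array_id,
    probe_id = as.character(raw$ID),
    spot_class = if ("SpotClass" %in% names(raw))
      as.character(raw$SpotClass) else "experimental",
    f_treat = raw[["F532 Median"]], b_treat = raw[["B532 Median"]],
    f_ctrl = raw[["F635 Median"]], b_ctrl = raw[["B635 Median"]],
    flag = ifelse(suppressWarnings(as.numeric(raw$Flags)) < 0, "bad", "good"),
    stringsAsFactors = FALSE)
  extras <- setdiff(names(raw), c(GPR_COLUMNS))
  for (cl in extras) out[[cl]] <- raw[[cl]]
  out
}

#' Write spot tables as GPR-like tab-delimited files
#'
#' Writes one file per array (named `<array_id>.gpr.txt`) with the canonical
#' column layout (`Block`, `Row`, `Column`, `ID`, `Name`, channel
#' foreground/background medians, `Flags`, `SpotClass`). Grid positions are
#' assigned sequentially in a 40-column layout.
#'
#' @param spots long spot table as produced by [generate_array_experiment()].
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of file paths written.
#' @export
write_spot_tables <- function(spots, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (aid in unique(spots$array_id)) {
    s <- spots[spots$array_id == aid, , drop = FALSE]
    n <- nrow(s)
    out <- data.frame(
      Block = 1L, Row = ((seq_len(n) - 1L) %/% 40L) + 1L,
      Column = ((seq_len(n) - 1L) %% 40L) + 1L,
      ID = s$probe_id, Name = s$probe_id,
      check.names = FALSE, stringsAsFactors = FALSE)
    out[["F532 Median"]] <- s$f_treat
    out[["B532 Median"]] <- s$b_treat
    out[["F635 Median"]] <- s$f_ctrl
    out[["B635 Median"]] <- s$b_ctrl
    out$Flags <- ifelse(s$flag == "bad", -100L, 0L)
    out$SpotClass <- s$spot_class
    p <- file.path(dir, paste0(aid, ".gpr.txt"))
    utils::write.table(out, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read and validate a sample sheet
#'
#' A sample sheet maps each array to its design cell: run, treatment, time
#' (hours) and biological replicate.
#'
#' @param path CSV file with columns `array_id`, `run`, `treatment`,
#'   `time_h`, `replicate`.
#' @param treatments,times_h optional vectors of admissible values; when
#'   given, unknown levels raise a validation error.
#' @return validated data.frame with a `design_cells` attribute summarising
#'   the design balance (cells x replicate counts).
#' @export
read_sample_sheet <- function(path, treatments = NULL, times_h = NULL) {
  if (!file.exists(path))
    stop("sample sheet not found: ", path, call. = FALSE)
  sheet <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_sample_sheet(sheet, treatments, times_h)
}

#' Validate an in-memory sample sheet
#' @param sheet data.frame with the four design columns plus `array_id`.
#' @inheritParams read_sample_sheet
#' @return the sheet, with a `design_cells` attribute.
#' @export
validate_sample_sheet <- function(sheet, treatments = NULL, times_h = NULL) {
  need <- c("array_id", "run", "treatment", "time_h", "replicate")
  missing_cols <- setdiff(need, names(sheet))
  if (length(missing_cols))
    stop("sample sheet missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (nrow(sheet) == 0)
    stop("sample sheet is empty", call. = FALSE)
  dup <- sheet$array_id[duplicated(sheet$array_id)]
  if (length(dup))
    stop("duplicate array_id in sample sheet: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  if (!is.null(treatments) && !all(sheet$treatment %in% treatments))
    stop("unknown treatment value(s): ",
         paste(setdiff(sheet$treatment, treatments), collapse = ", "),
         call. = FALSE)
  if (!is.null(times_h) && !all(sheet$time_h %in% times_h))
    stop("unknown time value(s): ",
         paste(setdiff(sheet$time_h, times_h), collapse = ", "),
         call. = FALSE)
  cells <- table(treatment = sheet$treatment, time_h = sheet$time_h,
                 run = sheet$run)
  attr(sheet, "design_cells") <- cells
  sheet
}

#' Write result tables and a reproducibility manifest
#'
#' Each element of `tables` is written as `<name>.csv` in `out_dir`; a
#' `manifest.json` records the file list with row counts, the options and seed
#' used, and the package version, so a run is reproducible from the manifest
#' alone.
#'
#' @param tables named list of data.frames.
#' @param out_dir output directory, created if needed.
#' @param options named list recorded verbatim in the manifest.
#' @param seed integer seed recorded in the manifest.
#' @return invisibly, the manifest as a list.
#' @export
write_results <- function(tables, out_dir, options = list(), seed = NULL) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, showWarnings = FALSE, recursive = TRUE))
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  stopifnot(is.list(tables), !is.null(names(tables)),
            all(nzchar(names(tables))))
  files <- list()
  for (nm in names(tables)) {
    tab <- as.data.frame(tables[[nm]])
    p <- file.path(out_dir, paste0(nm, ".csv"))
    utils::write.csv(tab, p, row.names = FALSE)
    files[[nm]] <- list(file = basename(p), rows = nrow(tab),
                        cols = ncol(tab))
  }
  manifest <- list(package = "dualstress",
                   version = as.character(utils::packageVersion("dualstress")),
                   seed = seed, options = options, files = files)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
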