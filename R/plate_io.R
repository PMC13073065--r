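# Canonical column sets for the interchange tables.
.TS_COLS <- c("plate", "row", "col", "strain", "condition_ugml", "time_h", "intensity")
.LAYOUT_COLS <- c("plate", "row", "col", "strain", "role")

.PLATE_ROWS <- 16L
.PLATE_COLS <- 24L

#' Convert between well-position strings and (row, col) indices
#'
#' 384-position arrays are indexed by row letters A-P (1-16) and 1-based
#' column numbers 1-24, the standard 384-well convention. `position_string()`
#' and `parse_position()` are exact inverses over this grid.
#'
#' @param row,col integer vectors of row (1-16) and column (1-24) indices.
#' @param pos character vector of position strings such as `"A1"`, `"P24"`.
#' @return `position_string()`: character vector; `parse_position()`: a
#'   data.frame with integer columns `row` and `col`.
#' @examples
#' position_string(1, 1)     # "A1"
#' parse_position("H23")     # row 8, col 23
#' @export
position_string <- function(row, col) {
  stopifnot(all(row >= 1L & row <= .PLATE_ROWS), all(col >= 1L & col <= .PLATE_COLS))
  paste0(LETTERS[row], col)
}

#' @rdname position_string
#' @export
parse_position <- function(pos) {
  m <- regmatches(pos, regexec("^([A-P])([0-9]{1,2})$", pos))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) {
    stop("invalid position string(s): ", paste(pos[bad], collapse = ", "))
  }
  row <- match(vapply(m, `[`, "", 2L), LETTERS)
  col <- as.integer(vapply(m, `[`, "", 3L))
  if (any(col < 1L | col > .PLATE_COLS)) {
    stop("column index out of range 1..", .PLATE_COLS)
  }
  data.frame(row = row, col = col)
}

.delim <- function(dialect) {
  dialect <- match.arg(dialect, c("tsv", "csv"))
  if (dialect == "tsv") "\t" else ","
}

# Read a delimited table, skipping "#" comment lines, with type checks that
# report the first offending data line (1-based, counting the header).
.read_table <- function(path, dialect, required, numeric_cols) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- .delim(dialect)
  df <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character", quote = "")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("schema error: missing required column(s): ", paste(missing, collapse = ", "))
  }
  for (nc in numeric_cols) {
    x <- suppressWarnings(as.numeric(df[[nc]]))
    bad <- which(is.na(x) & !(df[[nc]] %in% c("NA", "")))
    if (length(bad) > 0) {
      stop("parse error: non-numeric value in column '", nc, "' at data line ",
           bad[1] + 1L, " ('", df[[nc]][bad[1]], "')")
    }
    df[[nc]] <- x
  }
  df
}

# Numbers are serialized with %.17g so that write -> read round trips are
# bit-exact for doubles.
.fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

.write_table <- function(df, path, dialect = "tsv", comment = NULL) {
  sep <- .delim(dialect)
  out <- df
  for (nm in names(out)) {
    if (is.double(out[[nm]])) out[[nm]] <- .fmt_num(out[[nm]])
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(out, con, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

.pkg_stamp <- function(seed = NULL) {
  v <- as.character(utils::packageVersion("qhtcp"))
  s <- if (is.null(seed)) "NA" else as.character(seed)
  paste0("qhtcp ", v, " seed=", s)
}

#' Read and write spot-culture time-series tables
#'
#' The canonical interchange format is a long (tidy) delimited table with
#' columns `plate`, `row`, `col`, `strain`, `condition_ugml`, `time_h`,
#' `intensity`: one row per image of one spot culture. Tab-separated is the
#' default; comma-separated is accepted via `dialect = "csv"`. Lines starting
#' with `#` are comments.
#'
#' @param path file path.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @param series a time-series data.frame as returned by `read_timeseries()`.
#' @param seed optional integer recorded in the header comment of written
#'   files for provenance.
#' @return `read_timeseries()` returns a data.frame with the canonical
#'   columns (extra columns preserved), grouped by spot and sorted by time
#'   within each (plate, row, col, condition) spot.
#' @details Duplicated `(plate, row, col, condition_ugml, time_h)` rows are an
#'   error: each spot can only be imaged once per timepoint.
#' @export
read_timeseries <- function(path, dialect = "tsv") {
  df <- .read_table(path, dialect, .TS_COLS,
                    numeric_cols = c("col", "condition_ugml", "time_h", "intensity"))
  df$col <- as.integer(df$col)
  if (any(df$time_h < 0, na.rm = TRUE)) stop("negative time_h values")
  if (any(df$intensity < 0, na.rm = TRUE)) stop("negative intensity values")
  key <- paste(df$plate, df$row, df$col, df$condition_ugml, df$time_h, sep = "\r")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    stop("duplicate observation: (plate, row, col, condition, time) = (",
         gsub("\r", ", ", d, fixed = TRUE), ") appears more than once")
  }
  ord <- order(df$plate, df$condition_ugml, df$row, df$col, df$time_h)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' @rdname read_timeseries
#' @export
write_timeseries <- function(series, path, dialect = "tsv", seed = NULL) {
  stopifnot(all(.TS_COLS %in% names(series)))
  .write_table(series, path, dialect, comment = .pkg_stamp(seed))
}

#' Read and write 384-position plate layouts
#'
#' A layout maps every one of the 384 positions (rows A-P, columns 1-24) of a
#' plate to a strain identifier and a role: `deletion` (a gene deletion
#' strain), `reference` (the wild-type reference strain used for the z-score
#' denominator), or `empty`. A plate is either a deletion array (mixed
#' strains) or a reference array (all non-empty positions the same reference
#' strain).
#'
#' @param path file path.
#' @param dialect `"tsv"` or `"csv"`.
#' @param layout a layout data.frame.
#' @param seed optional integer for the provenance header.
#' @return a data.frame with columns `plate`, `row`, `col`, `strain`, `role`.
#' @export
read_layout <- function(path, dialect = "tsv") {
  df <- .read_table(path, dialect, .LAYOUT_COLS, numeric_cols = "col")
  df$col <- as.integer(df$col)
  validate_layout(df)
  df
}

#' @rdname read_layout
#' @export
write_layout <- function(layout, path, dialect = "tsv", seed = NULL) {
  stopifnot(all(.LAYOUT_COLS %in% names(layout)))
  .write_table(layout, path, dialect, comment = .pkg_stamp(seed))
}

#' Validate a plate layout table
#'
#' Checks the 384-position invariant (16 rows x 24 columns, each position
#' exactly once per plate), role values, and that reference arrays carry a
#' single strain.
#'
#' @param layout a layout data.frame (possibly several plates).
#' @return the layout, invisibly; errors describe the first violation.
#' @export
validate_layout <- function(layout) {
  if (!all(layout$role %in% c("deletion", "reference", "empty"))) {
    bad <- setdiff(unique(layout$role), c("deletion", "reference", "empty"))
    stop("invalid role value(s): ", paste(bad, collapse = ", "))
  }
  for (p in unique(layout$plate)) {
    sub <- layout[layout$plate == p, , drop = FALSE]
    if (nrow(sub) != .PLATE_ROWS * .PLATE_COLS) {
      stop("layout for plate '", p, "' has ", nrow(sub),
           " positions; expected ", .PLATE_ROWS * .PLATE_COLS)
    }
    pos <- paste(sub$row, sub$col)
    if (anyDuplicated(pos)) {
      stop("layout for plate '", p, "' has duplicated position(s)")
    }
    refs <- sub$strain[sub$role == "reference"]
    dels <- sub$role == "deletion"
    if (length(refs) > 0 && any(dels)) {
      stop("plate '", p, "' mixes reference and deletion roles")
    }
    if (length(refs) > 0 && length(unique(refs)) > 1) {
      stop("reference array '", p, "' carries more than one strain")
    }
  }
  invisible(layout)
}

#' Construct a screen design
#'
#' A screen design records the ordered set of drug concentrations (index 1
#' must be the untreated 0 condition) and an explicit manifest pairing each
#' deletion array with its matched reference array at each concentration.
#' Pairing is explicit rather than inferred so that mispairing cannot happen
#' silently.
#'
#' @param concentrations numeric vector of concentrations in ug/mL; the first
#'   element must be 0 (untreated).
#' @param manifest data.frame with columns `deletion_plate`,
#'   `condition_ugml`, `reference_plate`.
#' @return an object of class `screen_design`.
#' @export
screen_design <- function(concentrations = c(0, 10, 20), manifest) {
  stopifnot(is.numeric(concentrations), length(concentrations) >= 1)
  if (concentrations[1] != 0) {
    stop("the first (index 1) concentration must be 0 (untreated)")
  }
  if (anyDuplicated(concentrations)) stop("concentrations must be distinct")
  need <- c("deletion_plate", "condition_ugml", "reference_plate")
  if (!all(need %in% names(manifest))) {
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  }
  if (!all(manifest$condition_ugml %in% concentrations)) {
    stop("manifest contains conditions outside the design concentrations")
  }
  structure(list(concentrations = concentrations,
                 manifest = manifest[, need, drop = FALSE]),
            class = "screen_design")
}

#' @export
print.screen_design <- function(x, ...) {
  cat("screen_design:", length(x$concentrations), "concentrations (",
      paste(x$concentrations, collapse = ", "), "ug/mL ),",
      length(unique(x$manifest$deletion_plate)), "deletion plate(s)\n")
  invisible(x)
}

#' Validate a screen against its design
#'
#' Report-only consistency check: lists deletion arrays missing a design
#' condition, manifest rows whose reference array has no data, and layout
#' positions without any time-series data. Downstream scoring refuses plates
#' flagged here as incomplete.
#'
#' @param design a [screen_design()].
#' @param layouts layout data.frame covering all plates.
#' @param series long time-series data.frame.
#' @return a data.frame of issues with columns `plate`, `condition_ugml`,
#'   `issue`; zero rows when the screen is complete.
#' @export
validate_design <- function(design, layouts, series) {
  stopifnot(inherits(design, "screen_design"))
  issues <- list()
  add <- function(plate, cond, issue) {
    issues[[length(issues) + 1L]] <<- data.frame(
      plate = plate, condition_ugml = cond, issue = issue,
      stringsAsFactors = FALSE)
  }
  lay_err <- tryCatch({ validate_layout(layouts); NULL }, error = conditionMessage)
  if (!is.null(lay_err)) add(NA_character_, NA_real_, paste("layout invariant:", lay_err))

  man <- design$manifest
  have <- unique(series[, c("plate", "condition_ugml")])
  for (dp in unique(man$deletion_plate)) {
    for (conc in design$concentrations) {
      row <- man[man$deletion_plate == dp & man$condition_ugml == conc, , drop = FALSE]
      if (nrow(row) == 0) {
        add(dp, conc, "deletion array has no manifest entry for this condition")
        next
      }
      if (!any(have$plate == dp & have$condition_ugml == conc)) {
        add(dp, conc, "no time-series data for deletion array at this condition")
      }
      rp <- row$reference_plate[1]
      if (!any(have$plate == rp & have$condition_ugml == conc)) {
        add(rp, conc, "matched reference array has no time-series data")
      }
    }
  }

  # positions declared in layouts (non-empty) but absent from the data
  if (is.null(lay_err)) {
    nonempty <- layouts[layouts$role != "empty", , drop = FALSE]
    key_series <- unique(paste(series$plate, series$row, series$col, sep = "\r"))
    key_layout <- paste(nonempty$plate, nonempty$row, nonempty$col, sep = "\r")
    miss <- nonempty[!(key_layout %in% key_series) &
                       nonempty$plate %in% series$plate, , drop = FALSE]
    if (nrow(miss) > 0) {
      for (i in seq_len(nrow(miss))) {
        add(miss$plate[i], NA_real_,
            paste0("position ", miss$row[i], miss$col[i], " has no data"))
      }
    }
  }

  if (length(issues) == 0) {
    data.frame(plate = character(), condition_ugml = numeric(),
               issue = character(), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, issues)
  }
}

#' Read and write generic result tables
#'
#' All pipeline result tables (cell proliferation parameters, z-scores,
#' interactions, cluster assignments, enrichment) are written as TSV with a
#' leading `#` comment recording the package version and seed. Round trips
#' are lossless: doubles are serialized at full precision.
#'
#' @param df a data.frame.
#' @param path file path.
#' @param dialect `"tsv"` or `"csv"`.
#' @param seed optional integer for the provenance header.
#' @param numeric_cols character vector naming columns to parse as numeric on
#'   read; by default types are sniffed with `type.convert`.
#' @export
write_result_table <- function(df, path, dialect = "tsv", seed = NULL) {
  .write_table(df, path, dialect, comment = .pkg_stamp(seed))
}

#' @rdname write_result_table
#' @export
read_result_table <- function(path, dialect = "tsv", numeric_cols = NULL) {
  sep <- .delim(dialect)
  df <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character", quote = "")
  if (is.null(numeric_cols)) {
    for (nm in names(df)) {
      conv <- suppressWarnings(as.numeric(df[[nm]]))
      if (!anyNA(conv[!(df[[nm]] %in% c("NA", ""))])) {
        looks_num <- grepl("^[-+0-9.eEinfIN]", df[[nm]]) | df[[nm]] %in% c("NA", "")
        if (all(looks_num)) df[[nm]] <- conv
      }
    }
  } else {
    for (nm in numeric_cols) df[[nm]] <- as.numeric(df[[nm]])
  }
  df
}
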