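#' Define an odor panel
#'
#' An odor panel names the stimuli of a recording series, in presentation
#' order, and maps each odor to the solvent it was diluted in. The solvent
#' map drives solvent correction: the response to each diluted odor has the
#' response to its own solvent subtracted.
#'
#' @param odors Character vector of unique odor identifiers (e.g. `"C2"`,
#'   `"pyridine"`).
#' @param solvents Either a single solvent name applied to all odors, or a
#'   character vector named by odor giving each odor's solvent.
#' @return An object of class `odor_panel` with elements `odors` and
#'   `solvent_map` (character vector named by odor).
#' @examples
#' odor_panel(c("C2", "C4"), "water")
#' @seealso [default_acid_panel()]
#' @export
odor_panel <- function(odors, solvents = "water") {
  odors <- as.character(odors)
  if (length(odors) == 0L) stop("panel must contain at least one odor")
  if (anyDuplicated(odors)) {
    stop("odor identifiers must be unique: ",
         paste(unique(odors[duplicated(odors)]), collapse = ", "))
  }
  if (length(solvents) == 1L && is.null(names(solvents))) {
    solvent_map <- stats::setNames(rep(as.character(solvents), length(odors)), odors)
  } else {
    if (is.null(names(solvents))) {
      stop("'solvents' must be named by odor (or be a single solvent)")
    }
    missing <- setdiff(odors, names(solvents))
    if (length(missing)) {
      stop("no solvent given for odor(s): ", paste(missing, collapse = ", "))
    }
    solvent_map <- stats::setNames(as.character(solvents[odors]), odors)
  }
  structure(list(odors = odors, solvent_map = solvent_map), class = "odor_panel")
}

#' The linear carboxylic acid panel
#'
#' The standard stimulus panel for antennal coeloconic recordings: linear
#' carboxylic acids with one to six carbons (C1 = formic acid ... C6 =
#' hexanoic acid) dissolved in water, plus the diagnostic odors pyridine and
#' octanol dissolved in paraffin oil.
#'
#' @param diagnostics Logical; include the pyridine/octanol diagnostic odors
#'   (default `FALSE`, acids only).
#' @return An [odor_panel()].
#' @export
default_acid_panel <- function(diagnostics = FALSE) {
  odors <- paste0("C", 1:6)
  solv <- stats::setNames(rep("water", 6L), odors)
  if (diagnostics) {
    odors <- c(odors, "pyridine", "octanol")
    solv <- c(solv, pyridine = "paraffin oil", octanol = "paraffin oil")
  }
  odor_panel(odors, solv)
}

#' @export
print.odor_panel <- function(x, ...) {
  cat("Odor panel:", length(x$odors), "odors\n")
  cat(" ", paste0(x$odors, " (", x$solvent_map, ")", collapse = ", "), "\n")
  invisible(x)
}

make_row_ids <- function(genotype, sensillum) {
  ids <- paste(genotype, sensillum, sep = "|")
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    warning("duplicate (genotype, sensillum) pairs; adding numeric suffixes: ",
            paste(utils::head(dup, 5L), collapse = ", "), call. = FALSE)
    ids <- make.unique(ids, sep = "#")
  }
  ids
}

#' Construct a response matrix
#'
#' A response matrix holds solvent-corrected responses (spikes/s) of
#' individual sensilla (rows) to a panel of odors (columns). Missing cells
#' -- recordings lost, typically because the electrode came out of the
#' sensillum before the stimulus series finished -- are `NA`, never zero.
#'
#' @param values Numeric matrix, one row per sensillum, columns named by
#'   odor. `NA` marks missing cells.
#' @param genotype Character vector of genotype or species labels, one per
#'   row.
#' @param sensillum Optional sensillum identifiers, one per row; defaults to
#'   `s1, s2, ...` numbered within genotype.
#' @param panel Optional [odor_panel()]; when given, columns are reordered
#'   to the panel order and unknown columns are an error.
#' @return An object of class `response_matrix`: the numeric matrix with
#'   unique row ids and attributes `genotype`, `sensillum` and `panel`.
#' @export
response_matrix <- function(values, genotype, sensillum = NULL, panel = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(colnames(values))) stop("'values' must have odor column names")
  if (anyDuplicated(colnames(values))) stop("odor column names must be unique")
  genotype <- as.character(genotype)
  if (length(genotype) != nrow(values)) {
    stop("'genotype' must have one label per row")
  }
  if (is.null(sensillum)) {
    sensillum <- stats::ave(genotype, genotype,
                            FUN = function(g) paste0("s", seq_along(g)))
  }
  sensillum <- as.character(sensillum)
  if (length(sensillum) != nrow(values)) {
    stop("'sensillum' must have one id per row")
  }
  if (any(is.infinite(values))) stop("response values must be finite or NA")
  if (!is.null(panel)) {
    unknown <- setdiff(colnames(values), panel$odors)
    if (length(unknown)) {
      stop("odor column(s) not in panel: ", paste(unknown, collapse = ", "))
    }
    values <- values[, intersect(panel$odors, colnames(values)), drop = FALSE]
  }
  rownames(values) <- make_row_ids(genotype, sensillum)
  structure(values, genotype = genotype, sensillum = sensillum, panel = panel,
            class = c("response_matrix", "matrix", "array"))
}

#' @export
print.response_matrix <- function(x, ...) {
  cat(sprintf("Response matrix: %d sensilla x %d odors (%d genotypes, %d missing cells)\n",
              nrow(x), ncol(x), length(unique(attr(x, "genotype"))), sum(is.na(x))))
  print(utils::head(unclass(x)[, , drop = FALSE]), ...)
  if (nrow(x) > 6L) cat("...", nrow(x) - 6L, "more rows\n")
  invisible(x)
}

#' @export
as.data.frame.response_matrix <- function(x, ...) {
  data.frame(genotype = attr(x, "genotype"), sensillum = attr(x, "sensillum"),
             unclass(x), check.names = FALSE, row.names = NULL)
}

#' Genotype labels of a response matrix
#' @param x A `response_matrix`.
#' @return Character vector of per-row genotype/species labels.
#' @export
genotypes <- function(x) attr(x, "genotype")

detect_delim <- function(header) {
  if (grepl("\t", header, fixed = TRUE)) "\t" else ","
}

parse_response_cell <- function(cell) {
  cell <- trimws(cell)
  if (cell == "" || tolower(cell) == "nan" || is.na(cell)) return(NA_real_)
  suppressWarnings(v <- as.numeric(cell))
  v
}

#' Read a response table
#'
#' Reads a rectangular table of solvent-corrected responses in the
#' source-data dialect: one header row of odor names, genotype/species label
#' in the first column, an optional `sensillum` column, and the literal
#' `"NaN"` (any case) or an empty cell for missing data. The delimiter
#' (comma or tab) is auto-detected from the header line.
#'
#' @param path Path to a CSV/TSV file.
#' @param panel [odor_panel()] declaring the expected odor columns; a column
#'   not in the panel is an error.
#' @return A [response_matrix()] with columns in panel order.
#' @export
read_response_table <- function(path, panel) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (!inherits(panel, "odor_panel")) stop("'panel' must be an odor_panel")
  header <- readLines(path, n = 1L)
  sep <- detect_delim(header)
  raw <- utils::read.table(path, sep = sep, header = TRUE, colClasses = "character",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           na.strings = character(0))
  if (ncol(raw) < 2L) stop("table must have a label column and odor columns")
  label_col <- 1L
  cols <- colnames(raw)
  sens_col <- which(tolower(cols) == "sensillum")[1]
  odor_cols <- setdiff(seq_along(cols), c(label_col, sens_col))
  unknown <- setdiff(cols[odor_cols], panel$odors)
  if (length(unknown)) {
    stop("unknown odor column(s) not declared in panel: ",
         paste(unknown, collapse = ", "))
  }
  n <- nrow(raw)
  vals <- matrix(NA_real_, nrow = n, ncol = length(odor_cols),
                 dimnames = list(NULL, cols[odor_cols]))
  for (j in seq_along(odor_cols)) {
    cells <- raw[[odor_cols[j]]]
    for (i in seq_len(n)) {
      cell <- trimws(cells[i])
      if (cell == "" || tolower(cell) == "nan") next
      v <- suppressWarnings(as.numeric(cell))
      if (is.na(v)) {
        stop(sprintf("non-numeric cell '%s' at row %d, column '%s'",
                     cell, i, cols[odor_cols[j]]))
      }
      vals[i, j] <- v
    }
  }
  sens <- if (!is.na(sens_col)) raw[[sens_col]] else NULL
  response_matrix(vals, genotype = raw[[label_col]], sensillum = sens,
                  panel = panel)
}

#' Write a response table
#'
#' Writes a [response_matrix()] as CSV with the literal `NaN` for missing
#' cells and full double precision for values, so that
#' [read_response_table()] inverts it exactly (identical values and missing
#' mask).
#'
#' @param matrix A `response_matrix`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_response_table <- function(matrix, path) {
  if (!inherits(matrix, "response_matrix")) {
    stop("'matrix' must be a response_matrix")
  }
  fmt <- function(v) {
    out <- vapply(v, function(x) {
      if (is.na(x)) "NaN" else sprintf("%.17g", x)
    }, character(1))
    out
  }
  # genotype labels may contain the delimiter (e.g. "T289S,F538L"): CSV-quote
  quote_field <- function(x) paste0('"', gsub('"', '""', x), '"')
  cells <- apply(unclass(matrix), 2L, fmt)
  if (nrow(matrix) == 1L) cells <- matrix(cells, nrow = 1L,
                                          dimnames = list(NULL, colnames(matrix)))
  header <- paste(c("genotype", "sensillum", colnames(matrix)), collapse = ",")
  if (nrow(matrix) == 0L) {
    lines <- header
  } else {
    body <- apply(cbind(quote_field(attr(matrix, "genotype")),
                        quote_field(attr(matrix, "sensillum")),
                        cells), 1L, paste, collapse = ",")
    lines <- c(header, body)
  }
  con <- tryCatch(file(path, "w"), error = function(e) {
    stop("cannot open '", path, "' for writing: ", conditionMessage(e))
  })
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}
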