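# Readers and writers for the exchanged formats (feature tables, sample
# metadata, MGF spectra, TSV reports), the packaged reference fixtures, and
# the fragmentation-list dialect used in printed metabolite tables.
# All writers emit UTF-8, dot-decimal, tab-separated text with a header.

.read_delim_checked <- function(path, required, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          comment.char = "")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("file ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  df
}

.check_numeric <- function(df, cols, path) {
  for (cl in cols) {
    v <- suppressWarnings(as.numeric(df[[cl]]))
    bad <- which(is.na(v) & !is.na(df[[cl]]) & df[[cl]] != "NA")
    if (length(bad))
      stop("non-numeric value in ", path, ", column '", cl, "', row ",
           bad[1], ": '", df[[cl]][bad[1]], "'", call. = FALSE)
    df[[cl]] <- v
  }
  df
}

#' Read an LC-MS feature table
#'
#' Expects columns `feature_id`, `mz`, `rt`, followed by one intensity column
#' per sample id. Comma-separated for `.csv`, tab-separated otherwise.
#'
#' @param path Path to the delimited text file.
#' @return A data frame; intensity columns are numeric.
#' @export
read_features <- function(path) {
  df <- .read_delim_checked(path, c("feature_id", "mz", "rt"))
  if (anyDuplicated(df$feature_id))
    stop("duplicate feature ids in ", path, call. = FALSE)
  .check_numeric(df, setdiff(names(df), "feature_id"), path)
}

#' Write an LC-MS feature table
#'
#' @param features Data frame as returned by [read_features()].
#' @param path Output path (tab-separated).
#' @export
write_features <- function(features, path) {
  utils::write.table(features, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read sample metadata
#'
#' Expects columns `sample_id`, `group`, `tissue` and `creatinine` (urinary
#' creatinine concentration; may be NA for non-urine samples).
#'
#' @param path Path to the delimited text file.
#' @return A data frame.
#' @export
read_metadata <- function(path) {
  df <- .read_delim_checked(path, c("sample_id", "group", "tissue",
                                    "creatinine"))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample ids in ", path, call. = FALSE)
  .check_numeric(df, "creatinine", path)
}

#' Write sample metadata
#' @param metadata Data frame as returned by [read_metadata()].
#' @param path Output path (tab-separated).
#' @export
write_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read MS/MS spectra from an MGF file
#'
#' Minimal Mascot Generic Format reader: each `BEGIN IONS` block must carry a
#' `TITLE=` (used as the feature id) and may carry `PEPMASS=`; peak lines are
#' `m/z intensity` pairs. Intensities are rescaled to percent of base peak.
#'
#' @param path Path to the MGF file.
#' @return Named list of data frames (`mz`, `intensity_rel`) keyed by title,
#'   each with a `pepmass` attribute where present.
#' @export
read_mgf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (trimws(lines[i]) == "BEGIN IONS") {
      title <- NA_character_; pepmass <- NA_real_
      mz <- numeric(0); int <- numeric(0)
      i <- i + 1L
      while (i <= length(lines) && trimws(lines[i]) != "END IONS") {
        ln <- trimws(lines[i])
        if (startsWith(ln, "TITLE=")) title <- sub("^TITLE=", "", ln)
        else if (startsWith(ln, "PEPMASS="))
          pepmass <- as.numeric(strsplit(sub("^PEPMASS=", "", ln),
                                         "[ \t]")[[1]][1])
        else if (grepl("^[0-9]", ln)) {
          parts <- strsplit(ln, "[ \t]+")[[1]]
          mz <- c(mz, as.numeric(parts[1]))
          int <- c(int, as.numeric(parts[2]))
        }
        i <- i + 1L
      }
      if (i > length(lines))
        stop("truncated MGF: unterminated IONS block in ", path,
             call. = FALSE)
      if (is.na(title))
        stop("MGF block without TITLE in ", path, call. = FALSE)
      sp <- data.frame(mz = mz,
                       intensity_rel = if (length(int) && max(int) > 0)
                         int / max(int) * 100 else int)
      attr(sp, "pepmass") <- pepmass
      out[[title]] <- sp
    }
    i <- i + 1L
  }
  out
}

#' Write MS/MS spectra to an MGF file
#'
#' @param spectra Named list of data frames (`mz`, `intensity_rel`).
#' @param path Output path.
#' @param pepmass Optional named numeric vector of precursor m/z by title.
#' @export
write_mgf <- function(spectra, path, pepmass = NULL) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (title in names(spectra)) {
    sp <- spectra[[title]]
    writeLines("BEGIN IONS", con)
    writeLines(paste0("TITLE=", title), con)
    pm <- if (!is.null(pepmass) && title %in% names(pepmass))
      pepmass[[title]] else attr(sp, "pepmass")
    if (!is.null(pm) && length(pm) && !is.na(pm))
      writeLines(paste0("PEPMASS=", format(pm, digits = 10)), con)
    writeLines(sprintf("%.6f %.4f", sp$mz, sp$intensity_rel), con)
    writeLines("END IONS", con)
  }
  invisible(path)
}

#' Parse a printed fragmentation list
#'
#' Reads the compact dialect used in metabolite identification tables:
#' `"175.0230 (3); 113.0241 (35); ..."` -- m/z values each followed by a
#' parenthesized relative abundance, separated by semicolons (stray
#' delimiters are tolerated). `"n.d."` or an empty string yields `NULL`.
#'
#' @param text A single fragmentation string.
#' @return Data frame with `mz` and `intensity_rel`, or `NULL`.
#' @export
parse_fragment_string <- function(text) {
  if (is.na(text) || !nzchar(trimws(text)) || trimws(text) == "n.d.")
    return(NULL)
  m <- regmatches(text,
                  gregexpr("([0-9]+\\.?[0-9]*)\\s*\\(([0-9]+\\.?[0-9]*)\\)",
                           text))[[1]]
  if (!length(m))
    stop("unparseable fragmentation list: '", text, "'", call. = FALSE)
  mz <- as.numeric(sub("^([0-9.]+).*$", "\\1", m))
  rel <- as.numeric(sub("^.*\\(([0-9.]+)\\)$", "\\1", m))
  data.frame(mz = mz, intensity_rel = rel)
}

#' Write an annotation report
#'
#' @param hits An `annotation_hits` data frame.
#' @param path Output path (tab-separated, full precision).
#' @export
write_report <- function(hits, path) {
  utils::write.table(as.data.frame(hits), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a candidate library
#'
#' @param library A `candidate_library`.
#' @param path Output path (tab-separated).
#' @export
write_library <- function(library, path) {
  utils::write.table(as.data.frame(library), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Load a packaged reference fixture
#'
#' Two curated plain-text fixtures ship with the package:
#' \describe{
#'   \item{`"limonene_metabolites"`}{23 limonene metabolite features
#'     identified in mouse urine and liver by negative-mode LC-ESI-qToF
#'     suspect screening after 0.1% / 0.8% dietary supplementation: id,
#'     metabolite label, retention time, observed `[M-H]-` m/z, printed
#'     fragmentation list, reported ppm error, anion formula, percent of
#'     total urinary metabolite signal in each dose group, and tissue flags.}
#'   \item{`"essential_oil"`}{GC-MS characterization of the administered
#'     limonene-rich orange essential oil: 9 compounds with retention times
#'     and relative chromatographic peak areas.}
#' }
#'
#' @param name Fixture name.
#' @return A data frame.
#' @export
load_fixture <- function(name = c("limonene_metabolites", "essential_oil")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".tsv"), package = "suspectms",
                      mustWork = TRUE)
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "\"",
                          stringsAsFactors = FALSE, check.names = FALSE)
  df
}

#' MS/MS spectra of the metabolite fixture
#'
#' Parses the printed fragmentation lists of the
#' `"limonene_metabolites"` fixture into spectra keyed by feature id
#' (entries recorded as not detected are omitted).
#'
#' @param fixture Output of `load_fixture("limonene_metabolites")`.
#' @return Named list of data frames (`mz`, `intensity_rel`).
#' @export
fixture_spectra <- function(fixture = load_fixture("limonene_metabolites")) {
  out <- list()
  for (i in seq_len(nrow(fixture))) {
    sp <- parse_fragment_string(fixture$msms[i])
    if (!is.null(sp)) out[[fixture$id[i]]] <- sp
  }
  out
}
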