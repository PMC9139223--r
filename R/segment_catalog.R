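# IMGT functionality classes recognised throughout the package.
SEGMENT_FUNCTIONALITY <- c("functional", "pseudogene", "ORF")

#' Normalize a V/J segment name to IMGT long form
#'
#' Accepts the IMGT long form (`"TRAV12-1"`), the short form used in printed
#' repertoire tables (`"AV12-1"`, `"BJ2-1"`) and, when `locus` is supplied,
#' the bare form (`"V27"`, `"J43"`). Allele suffixes (`"*01"`) are stripped:
#' the package works at gene, not allele, resolution.
#'
#' @param name character vector of segment names.
#' @param locus optional locus (`"TRA"` or `"TRB"`) used to resolve bare
#'   `V`/`J` names that carry no locus letter.
#' @return character vector of canonical long-form names.
#' @examples
#' normalize_segment_name(c("AV12-1", "TRAV12-1", "BJ2-1"))
#' normalize_segment_name("V27", locus = "TRA")
#' @export
normalize_segment_name <- function(name, locus = NULL) {
  name <- sub("\\*.*$", "", trimws(as.character(name)))
  long <- grepl("^TR[AB][VJ]", name)
  short <- !long & grepl("^[AB][VJ]", name)
  bare <- !long & !short & grepl("^[VJ]", name)
  out <- name
  out[short] <- paste0("TR", name[short])
  if (any(bare)) {
    if (is.null(locus)) {
      stop("cannot resolve bare segment name(s) without a locus: ",
           paste(unique(name[bare]), collapse = ", "))
    }
    locus <- match.arg(locus, c("TRA", "TRB"))
    out[bare] <- paste0(locus, name[bare])
  }
  bad <- !grepl("^TR[AB][VJ].+", out) & nzchar(out)
  if (any(bad)) {
    stop("unparseable segment name(s): ",
         paste(unique(name[bad]), collapse = ", "))
  }
  out
}

segment_locus <- function(name) substr(name, 1L, 3L)
segment_type <- function(name) substr(name, 4L, 4L)

new_segment_catalog <- function(df, source_label = "unspecified") {
  rownames(df) <- NULL
  structure(df, class = c("segment_catalog", "data.frame"),
            source_label = source_label)
}

#' Load a germline segment catalog
#'
#' Reads a delimited file (TSV or CSV) with columns `name` and
#' `functionality`. The locus (TRA/TRB) and segment type (V/J) are inferred
#' from the name after normalization. The bundled fixture
#' `system.file("extdata", "imgt_fixture.tsv", package = "pairrep")` carries
#' an IMGT-style functionality assignment for the full TRAV/TRAJ/TRBV/TRBJ
#' universe, including the pseudogene and ORF segments excluded from
#' recombination counting.
#'
#' @param path path to the catalog file.
#' @return a `segment_catalog`: a data frame with columns `name`, `locus`,
#'   `segment_type`, `functionality`.
#' @export
load_catalog <- function(path) {
  if (!file.exists(path)) stop("catalog file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  raw <- utils::read.table(path, sep = sep, header = TRUE,
                           colClasses = "character",
                           comment.char = "#", quote = "",
                           blank.lines.skip = TRUE)
  names(raw) <- tolower(names(raw))
  for (col in c("name", "functionality")) {
    if (!col %in% names(raw)) stop("catalog file lacks column '", col, "'")
  }
  if (nrow(raw) == 0L) stop("catalog validation failed: no segments in ", path)
  fun <- raw$functionality
  canon <- SEGMENT_FUNCTIONALITY[match(tolower(fun),
                                       tolower(SEGMENT_FUNCTIONALITY))]
  if (anyNA(canon)) {
    stop("unknown functionality label(s): ",
         paste(unique(fun[is.na(canon)]), collapse = ", "))
  }
  name <- tryCatch(normalize_segment_name(raw$name), error = function(e) {
    bad <- which(!grepl("^(TR)?[AB][VJ]", trimws(raw$name)))
    stop("catalog line ", if (length(bad)) bad[1] + 1L else "?", ": ",
         conditionMessage(e), call. = FALSE)
  })
  df <- data.frame(name = name, locus = segment_locus(name),
                   segment_type = segment_type(name),
                   functionality = canon, stringsAsFactors = FALSE)
  key <- paste(df$locus, df$segment_type, df$name)
  if (anyDuplicated(key)) {
    stop("duplicate segment name(s) within a (locus, type): ",
         paste(unique(df$name[duplicated(key)]), collapse = ", "))
  }
  for (loc in unique(df$locus)) {
    for (ty in c("V", "J")) {
      n_fun <- sum(df$locus == loc & df$segment_type == ty &
                     df$functionality == "functional")
      if (n_fun == 0L) {
        stop("catalog validation failed: no functional ", loc, ty,
             " segment present")
      }
    }
  }
  new_segment_catalog(df, source_label = path)
}

#' Default bundled segment catalog
#'
#' @return the catalog loaded from the packaged `imgt_fixture.tsv`.
#' @export
default_catalog <- function() {
  load_catalog(system.file("extdata", "imgt_fixture.tsv",
                           package = "pairrep", mustWork = TRUE))
}

#' Filter a catalog by functionality class
#'
#' Pseudogene and ORF segments are excluded from usage and recombination
#' counting; `filter_segments(catalog, "functional")` performs that
#' exclusion. Order is preserved.
#'
#' @param catalog a `segment_catalog`.
#' @param keep character vector of functionality classes to retain.
#' @return the filtered `segment_catalog`.
#' @export
filter_segments <- function(catalog, keep = "functional") {
  if (length(keep) == 0L) stop("'keep' must name at least one class")
  keep <- match.arg(keep, SEGMENT_FUNCTIONALITY, several.ok = TRUE)
  new_segment_catalog(catalog[catalog$functionality %in% keep, , drop = FALSE],
                      source_label = attr(catalog, "source_label"))
}

#' Size of the V-J recombination space
#'
#' The number of distinct V-J recombinants over a filtered segment set,
#' i.e. the number of cells of the pairing matrix: `n_v * n_j`.
#'
#' @param n_v,n_j positive integer counts of V and J segments.
#' @return integer, `n_v * n_j`.
#' @examples
#' possible_recombinants(41, 50) # 2050 TRAV-TRAJ recombinants
#' possible_recombinants(50, 13) # 650 TRBV-TRBJ recombinants
#' @export
possible_recombinants <- function(n_v, n_j) {
  if (length(n_v) != 1L || length(n_j) != 1L ||
      !is.finite(n_v) || !is.finite(n_j) ||
      n_v < 1 || n_j < 1 || n_v != round(n_v) || n_j != round(n_j)) {
    stop("n_v and n_j must be positive integers")
  }
  as.integer(n_v) * as.integer(n_j)
}

# Functionality lookup for observed calls. Segments absent from the catalog
# are treated as functional (catalog drift tolerance) with a warning.
lookup_functionality <- function(calls, catalog) {
  idx <- match(calls, catalog$name)
  fun <- catalog$functionality[idx]
  if (anyNA(fun)) {
    unknown <- sort(unique(calls[is.na(fun)]))
    warning("segment(s) not in catalog, treated as functional: ",
            paste(unknown, collapse = ", "), call. = FALSE)
    fun[is.na(fun)] <- "functional"
  }
  fun
}

#' Segments of a catalog for one locus and type
#'
#' @param catalog a `segment_catalog`.
#' @param locus `"TRA"` or `"TRB"`.
#' @param segment_type `"V"` or `"J"`.
#' @return character vector of segment names, catalog order.
#' @export
catalog_segments <- function(catalog, locus, segment_type) {
  locus <- match.arg(locus, c("TRA", "TRB"))
  segment_type <- match.arg(segment_type, c("V", "J"))
  catalog$name[catalog$locus == locus & catalog$segment_type == segment_type]
}

#' @export
print.segment_catalog <- function(x, ...) {
  cat("Segment catalog (", attr(x, "source_label"), ")\n", sep = "")
  tab <- table(paste0(x$locus, x$segment_type), x$functionality)
  print(tab)
  invisible(x)
}
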