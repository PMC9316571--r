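#' Read a mature miRNA FASTA file into a validated RNA sequence set
#'
#' Reads miRBase-style FASTA (multi-line sequences allowed), takes the first
#' whitespace-delimited header token as the id, uppercases, and normalizes
#' to the RNA alphabet. All downstream analysis works on the returned
#' named [Biostrings::RNAStringSet].
#'
#' @param path path to a FASTA file.
#' @param alphabetPolicy how to treat symbols outside A/C/G/U:
#'   `"coerce_dna"` (default) substitutes T with U first, then errors on
#'   anything else; `"strict"` errors on any non-A/C/G/U symbol (including
#'   T); `"skip_invalid"` applies the T to U substitution, then drops (with
#'   a message) records that still contain other symbols.
#' @return a named [Biostrings::RNAStringSet]; ids are unique, sequences
#'   uppercase over A/C/G/U.
#' @details Duplicate ids are a hard error under every policy: presence
#'   counts are per-miRNA and a duplicated record would bias them.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">hsa-mir-765 example", "UGGAGGAGAAGGAAGGUGAUG"), fa)
#' set <- readMiRNAFasta(fa)
#' width(set)
#' @export
readMiRNAFasta <- function(path,
                           alphabetPolicy = c("coerce_dna", "strict",
                                              "skip_invalid")) {
  alphabetPolicy <- match.arg(alphabetPolicy)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) stop("no FASTA records in ", path)
  ids <- vapply(strsplit(names(raw), "\\s+"), `[`, "", 1L)
  if (any(!nzchar(ids))) stop("empty FASTA header in ", path)
  if (anyDuplicated(ids))
    stop("duplicate ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(as.character(raw))
  if (alphabetPolicy != "strict") seqs <- gsub("T", "U", seqs, fixed = TRUE)
  ok <- .isRnaString(seqs)
  if (!all(ok)) {
    if (alphabetPolicy == "skip_invalid") {
      message("dropping ", sum(!ok), " record(s) with non-RNA symbols: ",
              paste(head(ids[!ok], 5L), collapse = ", "))
      seqs <- seqs[ok]
      ids <- ids[ok]
      if (length(seqs) == 0L)
        stop("no valid records left in ", path, " after skipping")
    } else {
      stop("non-RNA symbols under policy '", alphabetPolicy, "' in: ",
           paste(head(ids[!ok], 5L), collapse = ", "))
    }
  }
  set <- Biostrings::RNAStringSet(setNames(seqs, ids))
  set
}

#' Write a sequence set as single-line FASTA
#'
#' Inverse of [readMiRNAFasta()]: ids and sequences round-trip exactly.
#' Sequences are written on one line each so identical sets produce
#' byte-identical files.
#'
#' @param set named RNAStringSet or named character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeMiRNAFasta <- function(set, path) {
  seqs <- .asSeqChar(set)
  writeLines(paste0(">", names(seqs), "\n", seqs), path, sep = "\n")
  invisible(path)
}

#' Read a miRNA-to-target-gene map
#'
#' Reads a two-column delimited file (miRNA id, gene symbol), one validated
#' interaction per line, emulating a miRTarBase export. The delimiter is
#' autodetected from the extension (`.csv` = comma, anything else = tab).
#' Repeated (id, gene) pairs collapse to one.
#'
#' @param path path to the file.
#' @param header `"auto"` (default: skip the first line when its fields
#'   look like column names such as "id"/"mirna" and "gene"/"target"),
#'   `TRUE`, or `FALSE`.
#' @return a [TargetMap-class].
#' @seealso [auditTargetMap()] to flag map ids absent from a sequence set.
#' @export
readTargetMap <- function(path, header = "auto") {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty target map file: ", path)
  fields <- strsplit(lines, sep, fixed = TRUE)
  bad <- which(lengths(fields) != 2L)
  if (length(bad))
    stop("malformed target map line ", bad[1L], " in ", path,
         " (expected 2 columns, got ", lengths(fields)[bad[1L]], ")")
  skip <- if (identical(header, "auto")) {
    f1 <- tolower(trimws(fields[[1L]]))
    f1[1L] %in% c("id", "mirna", "mir") &&
      f1[2L] %in% c("gene", "target", "symbol", "target_gene")
  } else isTRUE(header)
  if (skip) fields <- fields[-1L]
  if (length(fields) == 0L) stop("target map has a header but no rows: ", path)
  id <- trimws(vapply(fields, `[`, "", 1L))
  gene <- trimws(vapply(fields, `[`, "", 2L))
  if (any(!nzchar(id)) || any(!nzchar(gene)))
    stop("empty id or gene symbol in ", path)
  entries <- lapply(split(gene, id), function(g) sort(unique(g)))
  entries <- entries[order(names(entries), method = "radix")]
  new("TargetMap", entries = entries)
}

#' Build a target map in code
#'
#' @param entries named list: miRNA id -> character vector of gene symbols
#'   (deduplicated on construction).
#' @return a [TargetMap-class]
#' @export
targetMap <- function(entries) {
  entries <- lapply(entries, function(g) sort(unique(as.character(g))))
  entries <- entries[order(names(entries), method = "radix")]
  new("TargetMap", entries = entries)
}

#' Flag target-map ids absent from a sequence set
#'
#' Map entries whose miRNA id is not in the analyzed set are retained in
#' the map (they are valid interactions) but reported here so users can
#' audit id mismatches, e.g. precursor vs mature naming.
#'
#' @param map a [TargetMap-class]
#' @param set a sequence set
#' @return character vector of map ids absent from `set`
#' @export
auditTargetMap <- function(map, set) {
  seqs <- .asSeqChar(set)
  setdiff(names(map@entries), names(seqs))
}

#' Write a target map as two-column TSV (re-readable by [readTargetMap()])
#'
#' @param map a [TargetMap-class]
#' @param path output path
#' @return `path`, invisibly
#' @export
writeTargetMap <- function(map, path) {
  id <- rep(names(map@entries), lengths(map@entries))
  gene <- unlist(map@entries, use.names = FALSE)
  writeLines(c("id\tgene", paste(id, gene, sep = "\t")), path)
  invisible(path)
}
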