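# Promoter sets aligned on the TSS.
#
# Internal representation: plain character sequences plus a shared upstream
# extent. Position p of a base with 1-based string index i is p = i -
# upstream - 1, so the TSS base (first downstream base) is position 0.

#' Construct a TSS-aligned promoter set
#'
#' @param ids Character vector of unique promoter/gene identifiers.
#' @param sequences Character vector of DNA sequences over `A,C,G,T,N`
#'   (upper case), one per id.
#' @param upstream Number of bases upstream of the TSS shared by every
#'   record; the remaining bases of each record (its 5'UTR side) start at the
#'   TSS. Must satisfy `upstream < nchar(sequence)` for every record.
#' @param species Optional species label.
#' @return An object of class `promoter_set`.
#' @examples
#' ps <- promoter_set("p1", paste(rep("ACGT", 30), collapse = ""), upstream = 100)
#' ps
#' @export
promoter_set <- function(ids, sequences, upstream, species = "") {
  ids <- as.character(ids)
  sequences <- toupper(as.character(sequences))
  if (length(ids) != length(sequences))
    stop("'ids' and 'sequences' must have the same length")
  if (anyDuplicated(ids))
    stop("promoter ids must be unique; duplicated: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  upstream <- as.integer(upstream)
  if (length(upstream) != 1L || is.na(upstream) || upstream < 1L)
    stop("'upstream' must be a single positive integer")
  len <- nchar(sequences)
  if (any(len <= upstream))
    stop("records shorter than the TSS offset (no downstream base): ",
         paste(ids[len <= upstream], collapse = ", "))
  bad <- grepl("[^ACGTN]", sequences)
  if (any(bad))
    stop("invalid characters (only A,C,G,T,N allowed) in record(s): ",
         paste(ids[bad], collapse = ", "))
  structure(
    list(species = as.character(species)[1L],
         ids = ids,
         seq = sequences,
         upstream = upstream,
         downstream = as.integer(len - upstream)),
    class = "promoter_set")
}

#' @export
length.promoter_set <- function(x) length(x$ids)

#' @export
print.promoter_set <- function(x, ...) {
  cat(sprintf("promoter_set: %d promoters%s\n", length(x),
              if (nzchar(x$species)) paste0(" (", x$species, ")") else ""))
  cat(sprintf("  upstream extent: %d bases; 5'UTR side: %d-%d bases\n",
              x$upstream, min(x$downstream), max(x$downstream)))
  invisible(x)
}

#' Read a TSS-aligned promoter set from FASTA
#'
#' Reads a FASTA file of promoter sequences sharing a fixed upstream extent,
#' validates each record, and drops records that fail validation (short
#' 5'UTR, too many `N`s) while recording the reason. The TSS offset (number
#' of bases upstream of the TSS) is taken from `tss_offset` when supplied;
#' otherwise every record header must carry a `tss=<int>` annotation, and all
#' records must agree on it. Characters other than `A,C,G,T,N` are an error.
#'
#' @param path Path to a FASTA file (wrapped or unwrapped).
#' @param tss_offset Integer: bases upstream of the TSS in every record.
#'   Overrides per-record `tss=` header annotations when both are present.
#' @param species Species label stored on the set.
#' @param min_utr Minimum downstream (5'UTR side) length; shorter records are
#'   excluded (default 50, the conventional guard against truncated UTRs).
#' @param max_n_frac Maximum tolerated fraction of `N` bases per record
#'   (default 0.1); records above it are excluded.
#' @return A validated `promoter_set`. The full per-record validation table
#'   (id, length, upstream, downstream, status, reason) is attached as
#'   attribute `"validation"`; see [write_validation_report()].
#' @seealso [write_promoters()], [subtract_promoters()]
#' @export
read_promoters <- function(path, tss_offset = NULL, species = "",
                           min_utr = 50, max_n_frac = 0.1) {
  if (!file.exists(path)) stop("cannot read FASTA file: ", path)
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) stop("no FASTA records in ", path)
  headers <- names(raw)
  ids <- sub("\\s.*$", "", headers)
  seqs <- toupper(as.character(raw))
  names(seqs) <- NULL

  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop("record(s) with characters other than A,C,G,T,N: ",
         paste(ids[bad], collapse = ", "))

  if (is.null(tss_offset)) {
    m <- regmatches(headers, regexpr("tss=[0-9]+", headers))
    has <- grepl("tss=[0-9]+", headers)
    if (!all(has))
      stop("no global 'tss_offset' and record(s) without a tss= header: ",
           paste(ids[!has], collapse = ", "))
    offs <- as.integer(sub("tss=", "", m))
    if (length(unique(offs)) != 1L)
      stop("records disagree on tss=; a promoter set shares one upstream extent")
    tss_offset <- offs[1L]
  }
  tss_offset <- as.integer(tss_offset)
  len <- nchar(seqs)
  if (any(len < tss_offset))
    stop("record(s) shorter than tss_offset (", tss_offset, "): ",
         paste(ids[len < tss_offset], collapse = ", "))

  downstream <- len - tss_offset
  n_frac <- vapply(gregexpr("N", seqs, fixed = TRUE),
                   function(g) if (g[1L] == -1L) 0L else length(g), 0L) / len
  status <- rep("ok", length(ids))
  reason <- rep("", length(ids))
  short <- downstream < min_utr
  status[short] <- "excluded"
  reason[short] <- sprintf("5'UTR < %d", min_utr)
  manyn <- !short & n_frac > max_n_frac
  status[manyn] <- "excluded"
  reason[manyn] <- sprintf("N fraction > %g", max_n_frac)

  report <- data.frame(id = ids, length = len, upstream = tss_offset,
                       downstream = downstream, status = status,
                       reason = reason, stringsAsFactors = FALSE)
  keep <- status == "ok"
  if (!any(keep)) stop("promoter set empty after validation")
  set <- promoter_set(ids[keep], seqs[keep], upstream = tss_offset,
                      species = species)
  attr(set, "validation") <- report
  set
}

#' Write a promoter set as FASTA
#'
#' Headers carry the TSS offset as `tss=<upstream>` so the file round-trips
#' through [read_promoters()].
#'
#' @param set A `promoter_set`.
#' @param path Output file path.
#' @param width Line width for sequence wrapping; `Inf` writes one line per
#'   record.
#' @return `path`, invisibly.
#' @export
write_promoters <- function(set, path, width = 70) {
  stopifnot(inherits(set, "promoter_set"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_along(set$ids)) {
    writeLines(sprintf(">%s tss=%d", set$ids[i], set$upstream), con)
    s <- set$seq[i]
    if (is.finite(width)) {
      starts <- seq(1L, nchar(s), by = width)
      writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
    } else writeLines(s, con)
  }
  invisible(path)
}

#' Write the validation report of a promoter set as TSV
#'
#' @param set A `promoter_set` returned by [read_promoters()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_validation_report <- function(set, path) {
  rep <- attr(set, "validation")
  if (is.null(rep)) stop("set carries no validation report (not read from file?)")
  write.table(rep, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Remove promoters from a set by id
#'
#' Used by the discovery cascade to build nested promoter sets by successive
#' subtraction. Unknown ids are an error; the input set is not modified.
#'
#' @param set A `promoter_set`.
#' @param ids Identifiers to remove (may be empty).
#' @return A `promoter_set` without the listed promoters.
#' @export
subtract_promoters <- function(set, ids) {
  stopifnot(inherits(set, "promoter_set"))
  ids <- as.character(ids)
  unknown <- setdiff(ids, set$ids)
  if (length(unknown))
    stop("unknown promoter id(s): ", paste(unknown, collapse = ", "))
  keep <- !(set$ids %in% ids)
  out <- set
  out$ids <- set$ids[keep]
  out$seq <- set$seq[keep]
  out$downstream <- set$downstream[keep]
  attr(out, "validation") <- NULL
  out
}

# internal: subset by logical/integer index, keeping class
.subset_set <- function(set, keep) {
  out <- set
  out$ids <- set$ids[keep]
  out$seq <- set$seq[keep]
  out$downstream <- set$downstream[keep]
  attr(out, "validation") <- NULL
  out
}

#' Convert between string index and TSS-relative position
#'
#' Position 0 is the TSS base; upstream positions are negative. The string
#' index is 1-based.
#'
#' @param set A `promoter_set`.
#' @param index 1-based string index (for `position_of`).
#' @param position TSS-relative position (for `index_of`).
#' @return An integer vector.
#' @export
position_of <- function(set, index) as.integer(index) - set$upstream - 1L

#' @rdname position_of
#' @export
index_of <- function(set, position) as.integer(position) + set$upstream + 1L
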