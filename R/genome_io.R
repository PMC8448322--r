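# Reading and writing the standard formats the pipeline touches.
#
# Coordinate conventions, fixed package-wide: all positions are 0-based;
# BED intervals are half-open [start, end); conversion happens only here,
# at the I/O boundary.

#' Construct a genome object
#'
#' A genome is an ordered set of named chromosome sequences over the
#' alphabet A, C, G, T, N (uppercase).
#'
#' @param chroms named character vector, one uppercase sequence per
#'   chromosome.
#' @return an object of class `genome` with elements `chroms` (named
#'   character vector) and `lengths` (named integer vector, bp).
#' @export
genome <- function(chroms) {
  if (length(chroms) == 0L) stop("genome must contain at least one sequence")
  nms <- names(chroms)
  if (is.null(nms) || any(nms == "")) stop("all chromosomes must be named")
  if (anyDuplicated(nms)) {
    stop("duplicate chromosome name: ", nms[duplicated(nms)][1])
  }
  chroms <- toupper(chroms)
  if (any(nchar(chroms) == 0L)) stop("empty chromosome sequence")
  bad <- grepl("[^ACGTN]", chroms)
  if (any(bad)) {
    offending <- sub(".*?([^ACGTN]).*", "\\1", chroms[bad][1])
    stop("invalid character '", offending, "' in record '",
         nms[bad][1], "'")
  }
  structure(list(chroms = chroms, lengths = nchar(chroms)),
            class = "genome")
}

#' @export
print.genome <- function(x, ...) {
  cat("genome:", length(x$chroms), "chromosome(s),",
      sum(x$lengths), "bp total\n")
  for (nm in names(x$chroms)) cat("  ", nm, ": ", x$lengths[[nm]], " bp\n",
                                  sep = "")
  invisible(x)
}

#' Read a genome from a FASTA file
#'
#' Sequences are uppercased (soft-masked lowercase is kept as uppercase);
#' record order is preserved. Characters outside A/C/G/T/N raise an error
#' naming the offending character and record.
#'
#' @param path path to a FASTA file.
#' @return a [genome] object.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) stop("empty FASTA file: ", path)
  # FASTA description lines may carry comments after the record name
  nms <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(nms)) {
    stop("duplicate record name in FASTA: ", nms[duplicated(nms)][1])
  }
  chroms <- stats::setNames(as.character(seqs), nms)
  genome(chroms)
}

#' Write a genome to a FASTA file
#'
#' @param g a [genome] object.
#' @param path output path.
#' @param width line width in bp.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(g, path, width = 70L) {
  stopifnot(inherits(g, "genome"))
  set <- Biostrings::DNAStringSet(g$chroms)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Construct an annotation set of regulatory elements
#'
#' Truth elements are points: a promoter is anchored at its TSS with strand
#' `+` or `-`; an enhancer is anchored at its midpoint and is strandless
#' (`.`) because enhancers are bidirectionally transcribed.
#'
#' @param chrom,pos,class,strand,id parallel vectors: chromosome name,
#'   0-based position, class (`"promoter"`/`"enhancer"`), strand
#'   (`+`/`-`/`.`), record id.
#' @return a data frame of class `annotation_set`.
#' @export
annotation_set <- function(chrom = character(), pos = integer(),
                           class = character(), strand = character(),
                           id = as.character(seq_along(chrom))) {
  df <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                   class = as.character(class),
                   strand = as.character(strand),
                   id = as.character(id), stringsAsFactors = FALSE)
  if (nrow(df)) {
    if (!all(df$class %in% c("promoter", "enhancer"))) {
      stop("class must be 'promoter' or 'enhancer'")
    }
    if (!all(df$strand %in% c("+", "-", "."))) {
      stop("unknown strand symbol: ",
           setdiff(df$strand, c("+", "-", "."))[1])
    }
    bad <- df$class == "promoter" & df$strand == "."
    if (any(bad)) stop("promoters must have strand '+' or '-'")
    bad <- df$class == "enhancer" & df$strand != "."
    if (any(bad)) stop("enhancers must have strand '.'")
    if (any(df$pos < 0L)) stop("negative position in annotation set")
  }
  class(df) <- c("annotation_set", "data.frame")
  df
}

#' Read regulatory-element annotations from a BED6 file
#'
#' The element position is the interval midpoint `floor((start + end) / 2)`
#' in 0-based coordinates. Class is taken from an explicit 7th column when
#' present, otherwise inferred from the name prefix (`prom*` / `enh*`).
#'
#' @param path path to a BED file with at least 6 columns.
#' @return an [annotation_set].
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) return(annotation_set())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (any(ncols < 6L)) stop("BED line with fewer than 6 columns")
  start <- as.integer(vapply(fields, `[[`, "", 2L))
  end <- as.integer(vapply(fields, `[[`, "", 3L))
  if (any(start >= end)) {
    stop("empty or inverted BED interval (start >= end) at line ",
         which(start >= end)[1])
  }
  name <- vapply(fields, `[[`, "", 4L)
  strand <- vapply(fields, `[[`, "", 6L)
  cls <- vapply(fields, function(f) {
    if (length(f) >= 7L) f[[7L]] else NA_character_
  }, "")
  cls[is.na(cls) & startsWith(tolower(name), "prom")] <- "promoter"
  cls[is.na(cls) & startsWith(tolower(name), "enh")] <- "enhancer"
  if (anyNA(cls)) {
    stop("cannot infer class for record '", name[is.na(cls)][1],
         "': use a 'prom'/'enh' name prefix or an explicit 7th column")
  }
  annotation_set(chrom = vapply(fields, `[[`, "", 1L),
                 pos = (start + end) %/% 2L,
                 class = cls, strand = strand, id = name)
}

#' Write an annotation set as BED6 (+class column)
#'
#' @param ann an [annotation_set].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(ann, path) {
  stopifnot(inherits(ann, "annotation_set"))
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s\t%s",
                   ann$chrom, ann$pos, ann$pos + 1L, ann$id,
                   ann$strand, ann$class)
  writeLines(lines, path)
  invisible(path)
}

#' Write predictions as BED6 with a JSON score sidecar
#'
#' BED scores are `round(1000 * score)`; exact scores are preserved in a
#' parallel JSON report at `<path>.json`. Unsorted input is sorted on write
#' with a message.
#'
#' @param preds prediction data frame with columns `chrom`, `pos`, `score`,
#'   `strand` (as returned by [scan_genome()]).
#' @param path output BED path.
#' @return `path`, invisibly.
#' @export
write_predictions_bed <- function(preds, path) {
  stopifnot(is.data.frame(preds))
  if (nrow(preds)) {
    ord <- order(preds$chrom, preds$pos)
    if (!identical(ord, seq_len(nrow(preds)))) {
      message("predictions were not sorted by (chrom, pos); sorting on write")
      preds <- preds[ord, , drop = FALSE]
    }
    lines <- sprintf("%s\t%d\t%d\tpred_%d\t%d\t%s",
                     preds$chrom, preds$pos, preds$pos + 1L,
                     seq_len(nrow(preds)), as.integer(round(1000 * preds$score)),
                     preds$strand)
  } else {
    lines <- character()
  }
  writeLines(lines, path)
  jsonlite::write_json(
    list(n = nrow(preds),
         predictions = data.frame(chrom = preds$chrom, pos = preds$pos,
                                  score = round(preds$score, 3),
                                  strand = preds$strand)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Construct a position weight matrix
#'
#' @param name motif name.
#' @param matrix 4 x W column-stochastic probability matrix with rows
#'   A, C, G, T.
#' @param pseudocount pseudocount used when the matrix was derived from
#'   counts.
#' @return an object of class `pwm`.
#' @export
pwm <- function(name, matrix, pseudocount = 0.25) {
  if (!is.matrix(matrix) || nrow(matrix) != 4L) {
    stop("PWM matrix must have 4 rows (A, C, G, T)")
  }
  if (ncol(matrix) < 2L) stop("PWM width must be >= 2")
  sums <- colSums(matrix)
  if (any(abs(sums - 1) > 1e-6)) {
    stop("PWM columns must sum to 1 (max deviation ",
         format(max(abs(sums - 1))), ")")
  }
  rownames(matrix) <- BASES
  structure(list(name = name, matrix = matrix, pseudocount = pseudocount),
            class = "pwm")
}

#' Read position weight matrices from JASPAR or MEME-minimal text
#'
#' JASPAR count matrices are converted to column-stochastic probabilities
#' as `(count + pseudocount) / (colsum + 4 * pseudocount)`. MEME minimal
#' files already carry probabilities; the same pseudocount smoothing is
#' applied to guard against zero entries.
#'
#' @param path path to the motif file.
#' @param pseudocount pseudocount added before normalization.
#' @return a list of [pwm] objects.
#' @export
read_pwm <- function(path, pseudocount = 0.25) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  if (any(grepl("^MEME version", lines))) {
    return(parse_meme_minimal(lines, pseudocount))
  }
  parse_jaspar(lines, pseudocount)
}

normalize_counts <- function(counts, pseudocount) {
  widths <- unique(lengths(counts))
  if (length(widths) != 1L) stop("PWM rows of unequal width")
  mat <- do.call(rbind, counts)
  probs <- sweep(mat + pseudocount, 2, colSums(mat) + 4 * pseudocount, "/")
  probs
}

parse_jaspar <- function(lines, pseudocount) {
  headers <- grep("^>", lines)
  if (length(headers) == 0L) stop("no '>' headers found in PWM file")
  out <- list()
  bounds <- c(headers, length(lines) + 1L)
  for (i in seq_along(headers)) {
    name <- sub("^>\\s*", "", lines[headers[i]])
    name <- strsplit(name, "\\s+")[[1]][1]
    body <- lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)]
    counts <- stats::setNames(vector("list", 4), BASES)
    for (row in body) {
      base <- toupper(substr(row, 1, 1))
      if (!base %in% BASES) stop("unrecognized PWM row: ", row)
      nums <- regmatches(row, gregexpr("[0-9.]+", row))[[1]]
      counts[[base]] <- as.numeric(nums)
    }
    if (any(vapply(counts, is.null, logical(1)))) {
      stop("motif '", name, "' is missing one of the A/C/G/T rows")
    }
    probs <- normalize_counts(counts, pseudocount)
    out[[length(out) + 1L]] <- pwm(name, probs, pseudocount)
  }
  out
}

parse_meme_minimal <- function(lines, pseudocount) {
  starts <- grep("^MOTIF", lines)
  if (length(starts) == 0L) stop("no MOTIF entries in MEME file")
  out <- list()
  for (s in starts) {
    name <- strsplit(lines[s], "\\s+")[[1]][2]
    hdr <- s + which(startsWith(lines[(s + 1):length(lines)],
                                "letter-probability matrix"))[1]
    if (is.na(hdr)) stop("motif '", name, "' has no letter-probability matrix")
    rows <- list()
    i <- hdr + 1L
    while (i <= length(lines) && grepl("^[-0-9.eE+ \t]+$", lines[i])) {
      rows[[length(rows) + 1L]] <- as.numeric(strsplit(lines[i], "\\s+")[[1]])
      i <- i + 1L
    }
    if (length(unique(lengths(rows))) != 1L) stop("PWM rows of unequal width")
    # MEME rows are positions; transpose into 4 x W
    mat <- t(do.call(rbind, rows))
    probs <- normalize_counts(asplit(mat, 1), pseudocount)
    out[[length(out) + 1L]] <- pwm(name, probs, pseudocount)
  }
  out
}
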