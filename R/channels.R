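# Canonical 96-channel layout: six pyrimidine-referenced substitution classes,
# each expanded over the 16 flanking-base contexts (5' base major, 3' base minor).

SUBSTITUTIONS <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
DNA_BASES <- c("A", "C", "G", "T")

.make_channel_labels <- function() {
  labs <- character(96L)
  i <- 0L
  for (sub in SUBSTITUTIONS) {
    for (p5 in DNA_BASES) {
      for (p3 in DNA_BASES) {
        i <- i + 1L
        labs[i] <- paste0(p5, "[", sub, "]", p3)
      }
    }
  }
  labs
}

CHANNELS96 <- .make_channel_labels()

#' Canonical 96-channel labels
#'
#' Returns the fixed channel ordering used throughout the package: the six
#' substitution classes C>A, C>G, C>T, T>A, T>C, T>G, each expanded over the
#' sixteen trinucleotide contexts ordered by 5' base then 3' base
#' (`A[C>A]A`, `A[C>A]C`, ..., `T[T>G]T`). This matches the layout of the
#' COSMIC v2 signature tables.
#'
#' @return Character vector of length 96.
#' @export
channel_labels <- function() CHANNELS96

#' Reverse-complement DNA strings
#'
#' @param x Character vector of sequences over A/C/G/T (case-insensitive).
#' @return Character vector of reverse complements (uppercase).
#' @export
reverse_complement <- function(x) {
  comp <- chartr("ACGTacgt", "TGCATGCA", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(s) paste(rev(s), collapse = ""),
         character(1))
}

#' Classify substitutions into the 96 canonical channels
#'
#' Maps (ref, alt, trinucleotide context) triples onto the 96 canonical
#' pyrimidine-referenced channels. Purine-referenced mutations (ref A or G)
#' are reverse-complemented before lookup, so `G>T` in context `TGT` and
#' `C>A` in context `ACA` land on the same channel.
#'
#' @param ref,alt Single-base character vectors; `alt` must differ from `ref`.
#' @param context Character vector of 3-mers whose middle base equals `ref`.
#' @param on_error `"error"` to stop on an unclassifiable triple (ambiguous
#'   base, malformed context), `"na"` to return `NA` for it.
#' @return Integer vector of channel indices in 1..96 (see [channel_labels()]).
#' @export
classify_channel <- function(ref, alt, context, on_error = c("error", "na")) {
  on_error <- match.arg(on_error)
  n <- length(ref)
  stopifnot(length(alt) == n, length(context) == n)
  ref <- toupper(ref); alt <- toupper(alt); context <- toupper(context)

  bad <- !(ref %in% DNA_BASES) | !(alt %in% DNA_BASES) | ref == alt |
    nchar(context) != 3L | substr(context, 2L, 2L) != ref |
    !grepl("^[ACGT]{3}$", context)
  if (any(bad) && on_error == "error") {
    stop("unclassifiable substitution at position(s): ",
         paste(utils::head(which(bad), 5L), collapse = ", "),
         " (ambiguous base, ref == alt, or malformed context)")
  }

  # collapse purine-referenced records onto the pyrimidine strand
  flip <- ref %in% c("A", "G") & !bad
  if (any(flip)) {
    ref[flip] <- chartr("AG", "TC", ref[flip])
    alt[flip] <- chartr("ACGT", "TGCA", alt[flip])
    context[flip] <- reverse_complement(context[flip])
  }

  sub <- paste0(ref, ">", alt)
  sub_idx <- match(sub, SUBSTITUTIONS)
  p5_idx <- match(substr(context, 1L, 1L), DNA_BASES)
  p3_idx <- match(substr(context, 3L, 3L), DNA_BASES)
  idx <- 16L * (sub_idx - 1L) + 4L * (p5_idx - 1L) + p3_idx
  idx[bad] <- NA_integer_
  idx
}
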