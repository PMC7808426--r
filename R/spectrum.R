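# Six-class and 96-trinucleotide-context mutation spectra, with the usual
# pyrimidine-reference folding and cosine comparison between spectra.

.base_complement <- c(A = "T", C = "G", G = "C", T = "A")

.six_classes <- function() {
  c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
}

.bin_names_96 <- function() {
  bases <- c("A", "C", "G", "T")
  unlist(lapply(.six_classes(), function(cls) {
    as.vector(t(outer(bases, bases, function(f, t3)
      paste0(f, "[", cls, "]", t3))))
  }), use.names = FALSE)
}

.revcomp <- function(s) {
  vapply(strsplit(s, ""), function(b)
    paste(rev(unname(.base_complement[b])), collapse = ""), character(1))
}

#' Fold substitutions onto the pyrimidine reference strand
#'
#' Substitutions from a purine reference (A or G) are replaced by their
#' reverse complement so that every substitution is expressed with a C or T
#' reference; the trinucleotide context is reverse-complemented along with it.
#' Folding an already-folded record is a no-op.
#'
#' @param ref,alt,context character vectors (single bases; 3-base contexts
#'   whose middle base equals `ref`).
#' @return data.frame with folded `ref`, `alt`, `context`.
#' @export
fold_to_pyrimidine <- function(ref, alt, context) {
  bases <- names(.base_complement)
  ok <- ref %in% bases & alt %in% bases &
    !is.na(context) & nchar(context) == 3L &
    vapply(strsplit(context, ""), function(b) all(b %in% bases), logical(1))
  if (!all(ok)) stop("non-ACGT base or malformed context in records: ",
                     paste(which(!ok), collapse = ", "))
  if (any(substr(context, 2, 2) != ref)) {
    stop("context middle base must equal ref")
  }
  purine <- ref %in% c("A", "G")
  data.frame(
    ref = ifelse(purine, unname(.base_complement[ref]), ref),
    alt = ifelse(purine, unname(.base_complement[alt]), alt),
    context = ifelse(purine, .revcomp(context), context),
    stringsAsFactors = FALSE)
}

#' Mutation spectrum of a variant set
#'
#' Counts substitutions in the six pyrimidine-reference classes (C>A, C>G,
#' C>T, T>A, T>C, T>G) and the 96 class-by-flanking-base bins
#' (A[C>A]A ... T[T>G]T, COSMIC bin order). Purine-reference records are
#' reverse-complement folded first.
#'
#' @param records variant record data.frame with `ref`, `alt`, `context`.
#' @return object of class `mutation_spectrum`: list with named count vectors
#'   `six_class` and `ninety_six`, and the record count `n`.
#' @export
mutation_spectrum <- function(records) {
  folded <- fold_to_pyrimidine(records$ref, records$alt, records$context)
  cls <- paste0(folded$ref, ">", folded$alt)
  bins <- paste0(substr(folded$context, 1, 1), "[", cls, "]",
                 substr(folded$context, 3, 3))
  six <- table(factor(cls, levels = .six_classes()))
  n96 <- table(factor(bins, levels = .bin_names_96()))
  out <- list(six_class = stats::setNames(as.integer(six), names(six)),
              ninety_six = stats::setNames(as.integer(n96), names(n96)),
              n = nrow(records))
  stopifnot(sum(out$six_class) == out$n, sum(out$ninety_six) == out$n)
  structure(out, class = "mutation_spectrum")
}

#' Cosine similarity between two mutation spectra
#'
#' @param a,b `mutation_spectrum` objects (or bare named count vectors over
#'   the same bins).
#' @param bins which resolution to compare: the 96-bin vector (default) or
#'   the six-class vector.
#' @return cosine similarity in [0, 1].
#' @export
spectrum_similarity <- function(a, b, bins = c("ninety_six", "six_class")) {
  bins <- match.arg(bins)
  va <- if (inherits(a, "mutation_spectrum")) a[[bins]] else a
  vb <- if (inherits(b, "mutation_spectrum")) b[[bins]] else b
  if (length(va) != length(vb)) stop("spectra have different bin counts")
  na <- sqrt(sum(va^2)); nb <- sqrt(sum(vb^2))
  if (na == 0 || nb == 0) stop("cosine similarity undefined for an all-zero spectrum")
  sum(va * vb) / (na * nb)
}

#' @export
print.mutation_spectrum <- function(x, ...) {
  cat("mutation_spectrum of", x$n, "substitutions\n")
  print(x$six_class)
  invisible(x)
}
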