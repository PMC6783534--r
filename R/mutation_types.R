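#' Canonical 96 trinucleotide mutation classes
#'
#' Somatic single base substitutions are conventionally reported relative to
#' the pyrimidine of the mutated Watson-Crick pair, giving six substitution
#' classes (C>A, C>G, C>T, T>A, T>C, T>G) which, combined with the 5' and 3'
#' flanking bases, yield 96 classes. The ordering used throughout this
#' package is the COSMIC convention: substitution classes in the order
#' above, and within each class the 16 flank combinations with the 5' base
#' varying slowest, both flanks alphabetical.
#'
#' @return Character vector of length 96, e.g. `"A[C>A]A"`, in canonical
#'   order. All catalog, signature and exposure matrices in this package are
#'   indexed against this ordering.
#' @examples
#' head(mut_types_96())
#' @export
mut_types_96 <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  unlist(lapply(subs, function(s) {
    unlist(lapply(bases, function(p5) paste0(p5, "[", s, "]", bases)))
  }))
}

SUBSTITUTIONS_6 <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

BASES <- c("A", "C", "G", "T")
PURINES <- c("A", "G")
PYRIMIDINES <- c("C", "T")

#' Reverse complement of a base vector or string vector
#'
#' @param x character vector of DNA strings (A/C/G/T only).
#' @return character vector of reverse complements.
#' @keywords internal
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Classify a single base substitution into its 96-context class
#'
#' Substitutions with a purine reference base are mapped to the opposite
#' strand (reference, alternative and context are reverse-complemented)
#' so that every class is pyrimidine-centered. Vectorised over all
#' arguments.
#'
#' @param ref reference base(s), one of A/C/G/T.
#' @param alt alternative base(s), one of A/C/G/T, distinct from `ref`.
#' @param context trinucleotide context(s) on the plus strand; the center
#'   base must equal `ref`.
#' @return character vector of 96-class labels such as `"C[T>G]T"`.
#' @examples
#' classify_sbs("T", "G", "CTT") # "C[T>G]T"
#' classify_sbs("A", "C", "AAG") # same class, read from the other strand
#' @export
classify_sbs <- function(ref, alt, context) {
  n <- max(length(ref), length(alt), length(context))
  ref <- toupper(rep_len(ref, n))
  alt <- toupper(rep_len(alt, n))
  context <- toupper(rep_len(context, n))
  if (any(nchar(context) != 3L)) {
    stop("context must be a trinucleotide (length 3)")
  }
  ok_base <- function(b) b %in% BASES
  if (!all(ok_base(ref)) || !all(ok_base(alt))) {
    stop("ref and alt must be unambiguous bases (A/C/G/T)")
  }
  if (any(ref == alt)) {
    stop("ref and alt must differ")
  }
  if (any(!vapply(strsplit(context, ""), function(b) all(ok_base(b)), TRUE))) {
    stop("context contains an ambiguous base")
  }
  if (any(substr(context, 2L, 2L) != ref)) {
    stop("context center base must equal ref")
  }
  flip <- ref %in% PURINES
  if (any(flip)) {
    context[flip] <- revcomp(context[flip])
    ref[flip] <- revcomp(ref[flip])
    alt[flip] <- revcomp(alt[flip])
  }
  paste0(
    substr(context, 1L, 1L), "[", ref, ">", alt, "]",
    substr(context, 3L, 3L)
  )
}

#' Extract the substitution class (6 types) from a 96-class label
#'
#' @param types character vector of 96-class labels.
#' @return character vector drawn from the six pyrimidine substitution
#'   classes.
#' @export
substitution_of <- function(types) {
  sub("^.\\[(.>.)\\].$", "\\1", types)
}

#' 5' and 3' flanking bases of a 96-class label
#' @param types character vector of 96-class labels.
#' @return data.frame with columns `five_prime`, `substitution`,
#'   `three_prime`.
#' @export
split_type_96 <- function(types) {
  data.frame(
    five_prime = substr(types, 1L, 1L),
    substitution = substitution_of(types),
    three_prime = substr(types, nchar(types), nchar(types)),
    stringsAsFactors = FALSE
  )
}
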