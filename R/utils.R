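#' Reverse complement of DNA sequences
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements; non-ACGT characters
#'   become N.
#' @export
revcomp <- function(x) {
  .revcomp_cpp(as.character(x))
}

#' Convert between DNA and RNA alphabets
#'
#' Sequences are stored internally in the DNA alphabet (U is converted to T
#' on ingest); reports and sequence logos render RNA.
#'
#' @param x character vector.
#' @return character vector in the other alphabet.
#' @export
dna_to_rna <- function(x) chartr("Tt", "Uu", x)

#' @rdname dna_to_rna
#' @export
rna_to_dna <- function(x) chartr("Uu", "Tt", x)

# deterministic per-task seed derived from a master seed; stays < 2^31
derive_seed <- function(seed, ...) {
  parts <- c(seed, unlist(list(...)))
  h <- 0
  for (p in parts) {
    v <- if (is.character(p)) sum(utf8ToInt(p)) else as.numeric(p)
    h <- (h * 31 + v) %% 2147483399
  }
  as.integer(h + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
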