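# Pairwise alignment substrate shared by the comparison and clustering
# layers. Wraps Biostrings global alignment with a flat +1/-1 scoring
# scheme and affine gaps.

#' Alignment scoring parameters
#'
#' Flat scoring used throughout the package: match +1, mismatch -1,
#' affine gaps with open cost 2 and extension cost 1 per column (a gap
#' of length L costs 2 + L). Global (end-to-end) alignment only.
#'
#' @param match Match score (> 0).
#' @param mismatch Mismatch score.
#' @param gap_open Gap opening cost (>= 0, subtracted).
#' @param gap_extend Gap extension cost per column (>= 0, subtracted).
#' @return A list of class \code{alignment_params}.
#' @export
alignment_params <- function(match = 1, mismatch = -1, gap_open = 2,
                             gap_extend = 1) {
  if (match <= 0) stop_arg("match score must be positive")
  if (gap_open < 0 || gap_extend < 0)
    stop_arg("gap costs are given as non-negative penalties")
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend, mode = "global"),
            class = "alignment_params")
}

# flat substitution matrix over an explicit alphabet
.flat_submat <- function(alphabet, match, mismatch) {
  n <- length(alphabet)
  m <- matrix(mismatch, n, n, dimnames = list(alphabet, alphabet))
  diag(m) <- match
  m
}

.aa_alphabet <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X", "B", "Z", "U", "O", "*")
.nt_alphabet <- c("A", "C", "G", "T", "N")

.submat_for <- function(alphabet, params) {
  .flat_submat(alphabet, params$match, params$mismatch)
}

# Global alignment of one or many pattern sequences against one subject.
# Returns a data.frame with identity (identical columns / alignment
# columns), coverage (aligned columns of the shorter sequence / its
# length), and score.
.align_global <- function(patterns, subject, params, alphabet) {
  aln <- Biostrings::pairwiseAlignment(
    patterns, subject,
    substitutionMatrix = .submat_for(alphabet, params),
    gapOpening = params$gap_open, gapExtension = params$gap_extend,
    type = "global")
  # alignedPattern/alignedSubject include end gaps, unlike nchar(aln)
  ap <- Biostrings::alignedPattern(aln)
  as_ <- Biostrings::alignedSubject(aln)
  ncols <- Biostrings::width(ap)
  nmat <- Biostrings::nmatch(aln)
  gaps_p <- as.vector(Biostrings::letterFrequency(ap, "-"))
  gaps_s <- as.vector(Biostrings::letterFrequency(as_, "-"))
  aligned_cols <- ncols - gaps_p - gaps_s
  shorter <- pmin(nchar(patterns), nchar(subject))
  data.frame(identity = nmat / ncols,
             coverage = aligned_cols / shorter,
             score = Biostrings::score(aln))
}

#' Global protein identity and coverage
#'
#' Optimal global alignment of two amino-acid sequences under
#' \code{\link{alignment_params}}. Identity is identical columns divided
#' by total alignment columns (gap columns included); coverage is the
#' number of aligned (non-gap-vs-gap) columns of the shorter sequence
#' divided by its length.
#'
#' @param a,b Amino-acid sequences (non-empty strings).
#' @param params An \code{\link{alignment_params}}.
#' @return Named numeric vector \code{c(identity=, coverage=)}.
#' @examples
#' protein_identity("ACDEFG", "ACDEAG")  # identity 5/6
#' @export
protein_identity <- function(a, b, params = alignment_params()) {
  if (!nzchar(a) || !nzchar(b)) stop_arg("sequences must be non-empty")
  # canonical orientation: exact symmetry even under alignment ties
  if (b < a) { tmp <- a; a <- b; b <- tmp }
  r <- .align_global(a, b, params, .aa_alphabet)
  c(identity = r$identity[1L], coverage = min(r$coverage[1L], 1))
}

# vectorized many-vs-one protein alignment (internal fast path)
.protein_identity_many <- function(patterns, subject, params) {
  r <- .align_global(patterns, subject, params, .aa_alphabet)
  r$coverage <- pmin(r$coverage, 1)
  r
}

# vectorized many-vs-one nucleotide alignment (internal fast path)
.nt_identity_many <- function(patterns, subject, params) {
  r <- .align_global(patterns, subject, params, .nt_alphabet)
  r$coverage <- pmin(r$coverage, 1)
  r
}
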