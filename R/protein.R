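#' @include AllClasses.R
NULL

AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# average residue masses (Da); MW = sum(residues) + one water
.AA_MASS <- c(A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886,
              C = 103.1388, E = 129.1155, Q = 128.1307, G = 57.0519,
              H = 137.1411, I = 113.1594, L = 113.1594, K = 128.1741,
              M = 131.1926, F = 147.1766, P = 97.1167, S = 87.0782,
              T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)

.pkaCache <- new.env(parent = emptyenv())

#' Ionizable-group pKa tables
#'
#' Returns the bundled pKa table for one named set. The default
#' `"bjellqvist"` set (N-terminus 7.5, C-terminus 3.55, side chains C 9.0,
#' D 4.05, E 4.45, H 5.98, K 10.0, R 12.0, Y 10.0) is the convention used
#' by common pI servers; `"emboss"` is provided as an alternative. The
#' tables ship as a versioned data file so results are reproducible.
#'
#' @param set `"bjellqvist"` (default) or `"emboss"`.
#' @return data.frame with columns `group`, `sign` (`"pos"`/`"neg"`),
#'   `pka`.
#' @export
pkaTable <- function(set = "bjellqvist") {
  if (is.null(.pkaCache$tab)) {
    path <- system.file("extdata", "pka_sets.csv", package = "HaloScreen",
                        mustWork = TRUE)
    .pkaCache$tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  out <- .pkaCache$tab[.pkaCache$tab$set == set, c("group", "sign", "pka")]
  if (!nrow(out)) stop("unknown pKa set: ", set)
  rownames(out) <- NULL
  out
}

# validate and explode a one-letter sequence; invalid residues are
# rejected with their positions
.checkSequence <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  res <- strsplit(toupper(sequence), "")[[1]]
  if (!length(res)) stop("sequence is empty")
  bad <- which(!res %in% AA_STANDARD)
  if (length(bad))
    stop(sprintf("invalid residue(s) %s at position(s) %s",
                 paste(unique(res[bad]), collapse = ", "),
                 paste(bad, collapse = ", ")))
  res
}

#' Net charge of a protein at a given pH
#'
#' Henderson-Hasselbalch summation over the N-terminus, the C-terminus
#' and the ionizable side chains (D, E, C, Y, H, K, R): each positive
#' group contributes `+1 / (1 + 10^(pH - pKa))`, each negative group
#' `-1 / (1 + 10^(pKa - pH))`. The result is the expected net charge in
#' elementary charges; it is strictly decreasing in pH.
#'
#' @param sequence one-letter amino-acid sequence (20 standard residues;
#'   anything else is rejected with its position).
#' @param pH pH value(s) in [0, 14].
#' @param pkaSet name of the pKa set, see [pkaTable()].
#' @return numeric net charge, one value per pH.
#' @examples
#' netCharge("ACDEFGHIKLMNPQRSTVWY", 7.0)
#' @export
netCharge <- function(sequence, pH, pkaSet = "bjellqvist") {
  res <- .checkSequence(sequence)
  stopifnot(all(pH >= 0 & pH <= 14))
  tab <- pkaTable(pkaSet)
  counts <- table(factor(res, levels = AA_STANDARD))
  vapply(pH, function(ph) {
    q <- 0
    for (i in seq_len(nrow(tab))) {
      grp <- tab$group[i]
      nGrp <- if (grp == "Nterm" || grp == "Cterm") 1L
              else as.integer(counts[[grp]])
      if (nGrp == 0L) next
      q <- q + if (tab$sign[i] == "pos") {
        nGrp / (1 + 10^(ph - tab$pka[i]))
      } else {
        -nGrp / (1 + 10^(tab$pka[i] - ph))
      }
    }
    q
  }, numeric(1))
}

#' Isoelectric point of a protein
#'
#' The pH at which [netCharge()] is zero, found by bisection over
#' [0, 14]; the net charge is strictly decreasing in pH, so the root is
#' unique.
#'
#' @inheritParams netCharge
#' @param tol absolute charge tolerance at the returned pH.
#' @return pI in pH units.
#' @examples
#' isoelectricPoint("KKKKDD")
#' @export
isoelectricPoint <- function(sequence, pkaSet = "bjellqvist", tol = 1e-4) {
  .checkSequence(sequence)
  lo <- 0; hi <- 14
  qlo <- netCharge(sequence, lo, pkaSet)
  qhi <- netCharge(sequence, hi, pkaSet)
  if (qlo <= 0) return(lo)
  if (qhi >= 0) return(hi)
  for (it in 1:200) {
    mid <- (lo + hi) / 2
    q <- netCharge(sequence, mid, pkaSet)
    if (abs(q) < tol) return(mid)
    if (q > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Molecular weight of a protein
#'
#' Sum of average residue masses plus one water (Da).
#'
#' @inheritParams netCharge
#' @return molecular weight in Daltons.
#' @export
molecularWeight <- function(sequence) {
  res <- .checkSequence(sequence)
  sum(.AA_MASS[res]) + 18.01524
}

#' Read protein sequences from FASTA
#'
#' Thin wrapper over Biostrings that validates every sequence against the
#' 20-residue standard alphabet.
#'
#' @param path FASTA file path.
#' @return named character vector of sequences.
#' @export
readProteinFasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  seqs <- stats::setNames(as.character(aa), names(aa))
  for (nm in names(seqs)) .checkSequence(seqs[[nm]])
  seqs
}

#' Protein characteristics table
#'
#' Computes, per sequence, the molecular weight, the isoelectric point
#' and the net charge at a chosen pH -- the characteristics used to
#' interpret non-specific electrostatic binding: a protein with a pI
#' above the buffer pH carries a positive net charge there and is prone
#' to non-specific electrostatic binding of the (negatively charged)
#' aptamer DNA.
#'
#' @param sequences named character vector of sequences (e.g. from
#'   [readProteinFasta()]).
#' @param pH buffer pH at which to report the net charge (default 7.4).
#' @inheritParams netCharge
#' @return data.frame: `name`, `length`, `mw_da`, `pi`, `charge_at_pH`.
#' @export
proteinProperties <- function(sequences, pH = 7.4, pkaSet = "bjellqvist") {
  stopifnot(length(sequences) >= 1L)
  if (is.null(names(sequences)))
    names(sequences) <- sprintf("seq%02d", seq_along(sequences))
  out <- do.call(rbind, lapply(names(sequences), function(nm) {
    s <- sequences[[nm]]
    data.frame(name = nm, length = nchar(s), mw_da = molecularWeight(s),
               pi = isoelectricPoint(s, pkaSet),
               charge_at_pH = netCharge(s, pH, pkaSet),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
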