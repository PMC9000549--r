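# Peptide net charge and isoelectric point (Henderson-Hasselbalch).
# Used to characterize helix electrostatics: the acidic S3 helix versus
# the strongly basic, arginine-rich S4.

#' Bundled sidechain/termini pKa tables
#'
#' Two standard sets are provided: `"emboss"` (EMBOSS defaults) and
#' `"lehninger"` (textbook free-amino-acid values). Each table lists the
#' basic groups (N-terminus, Lys, Arg, His) and acidic groups
#' (C-terminus, Asp, Glu, Cys, Tyr).
#'
#' @param name `"emboss"` or `"lehninger"`.
#' @return list with numeric vectors `basic` and `acidic` (names are
#'   one-letter residue codes plus `Nterm`/`Cterm`).
#' @export
pka_table <- function(name = c("emboss", "lehninger")) {
  name <- match.arg(name)
  switch(name,
    emboss = list(
      basic = c(Nterm = 8.6, K = 10.8, R = 12.5, H = 6.5),
      acidic = c(Cterm = 3.6, D = 3.9, E = 4.1, C = 8.5, Y = 10.1)),
    lehninger = list(
      basic = c(Nterm = 9.69, K = 10.53, R = 12.48, H = 6.0),
      acidic = c(Cterm = 2.34, D = 3.86, E = 4.25, C = 8.33, Y = 10.07)))
}

.aa_alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

check_sequence <- function(seq) {
  s <- strsplit(toupper(gsub("\\s", "", seq)), "")[[1]]
  bad <- setdiff(unique(s), .aa_alphabet)
  if (length(bad))
    stop("unknown residue letter(s): ", paste(bad, collapse = ", "))
  s
}

#' Net peptide charge at a given pH
#'
#' Henderson-Hasselbalch sum: each basic group contributes
#' `+1/(1 + 10^(pH - pKa))`, each acidic group `-1/(1 + 10^(pKa - pH))`.
#'
#' @param seq one-letter amino-acid string.
#' @param pH pH value(s) in `[0, 14]`.
#' @param pka a table from [pka_table()] or its name.
#' @param include_termini include the free N/C termini (default TRUE).
#' @return net charge (vectorized over `pH`).
#' @export
net_charge_at_pH <- function(seq, pH, pka = "emboss",
                             include_termini = TRUE) {
  if (any(pH < 0 | pH > 14)) stop("pH must lie in [0, 14]")
  if (is.character(pka)) pka <- pka_table(pka)
  s <- check_sequence(seq)
  counts <- table(factor(s, levels = .aa_alphabet))
  vapply(pH, function(p) {
    pos <- 0; neg <- 0
    for (g in names(pka$basic)) {
      n <- if (g == "Nterm") as.numeric(include_termini) else counts[[g]]
      pos <- pos + n / (1 + 10^(p - pka$basic[[g]]))
    }
    for (g in names(pka$acidic)) {
      n <- if (g == "Cterm") as.numeric(include_termini) else counts[[g]]
      neg <- neg + n / (1 + 10^(pka$acidic[[g]] - p))
    }
    pos - neg
  }, numeric(1))
}

#' Isoelectric point of a peptide
#'
#' Bisection root of [net_charge_at_pH()] on `[0, 14]`. When the charge
#' curve does not change sign on that interval (no ionizable groups of one
#' kind) the nearer boundary is returned with a warning.
#'
#' @inheritParams net_charge_at_pH
#' @param tol pH tolerance of the bisection (default 1e-6).
#' @return pI in pH units.
#' @export
isoelectric_point <- function(seq, pka = "emboss", include_termini = TRUE,
                              tol = 1e-6) {
  if (is.character(pka)) pka <- pka_table(pka)
  f <- function(p) net_charge_at_pH(seq, p, pka, include_termini)
  lo <- 0; hi <- 14
  flo <- f(lo); fhi <- f(hi)
  if (flo <= 0) {
    warning("charge non-positive over [0, 14]; pI at boundary 0")
    return(0)
  }
  if (fhi >= 0) {
    warning("charge non-negative over [0, 14]; pI at boundary 14")
    return(14)
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Read amino-acid sequences from a FASTA file
#'
#' Thin wrapper over [seqinr::read.fasta()].
#'
#' @param path FASTA file.
#' @return named character vector of upper-case sequences.
#' @export
read_fasta_sequences <- function(path) {
  s <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                          set.attributes = FALSE)
  if (length(s) == 0) stop("no sequences in ", path)
  out <- toupper(unlist(s))
  names(out) <- names(s)
  out
}
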