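# Sequence arithmetic: ORF -> protein length, standard-code translation,
# and average protein molecular mass.

# NCBI standard genetic code (table 1), stop = "*"
.codon_table <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G"
)

# Isotope-averaged residue masses (Da): amino acid minus one water, the
# standard values used by protein mass calculators.
.residue_mass <- c(
  G = 57.0519,  A = 71.0788,  S = 87.0782,  P = 97.1167,  V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132
)

.water_mass <- 18.0153

#' Protein length implied by an ORF length
#'
#' An open reading frame of `n` base pairs (start codon through stop codon)
#' encodes `n/3 - 1` amino acids: one residue per codon, minus the stop.
#'
#' @param orf_length_bp ORF length in base pairs; must be divisible by 3 and
#'   at least 6.
#' @return Amino-acid count.
#' @examples
#' orf_protein_length(1137)  # 378
#' @export
orf_protein_length <- function(orf_length_bp) {
  if (any(!is.finite(orf_length_bp)) || any(orf_length_bp < 6))
    stop("orf_protein_length: ORF must be at least 6 bp", call. = FALSE)
  if (any(orf_length_bp %% 3 != 0))
    stop("orf_protein_length: ORF length must be divisible by 3",
         call. = FALSE)
  as.integer(orf_length_bp / 3 - 1)
}

# normalize a nucleotide string: uppercase, U -> T, reject anything else
.clean_orf <- function(nt) {
  nt <- chartr("u", "U", toupper(nt))
  nt <- gsub("U", "T", nt, fixed = TRUE)
  if (grepl("[^ACGT]", nt))
    stop("sequence error: non-ACGT character in ORF", call. = FALSE)
  nt
}

#' Translate an ORF with the standard genetic code
#'
#' Translates a full open reading frame (NCBI translation table 1),
#' removing the trailing stop codon. Input is uppercased and `U` is
#' normalized to `T`; ambiguous bases and internal stop codons are errors.
#'
#' @param orf Nucleotide string over A/C/G/T (case-insensitive; RNA
#'   accepted).
#' @return Protein string in one-letter code.
#' @examples
#' translate_orf("ATGAAATAA")  # "MK"
#' @export
translate_orf <- function(orf) {
  stopifnot(is.character(orf), length(orf) == 1L)
  nt <- .clean_orf(orf)
  n <- nchar(nt)
  if (n %% 3 != 0 || n < 6)
    stop("sequence error: ORF length must be a multiple of 3 and >= 6",
         call. = FALSE)
  codons <- substring(nt, seq(1, n, 3), seq(3, n, 3))
  aa <- .codon_table[codons]
  k <- length(aa)
  if (aa[k] != "*")
    stop("sequence error: ORF does not end with a stop codon", call. = FALSE)
  aa <- aa[-k]
  if (any(aa == "*"))
    stop("sequence error: internal stop codon", call. = FALSE)
  paste(aa, collapse = "")
}

#' Average molecular mass of a protein
#'
#' Sum of isotope-averaged residue masses plus one water (18.0153 Da), the
#' convention under which masses are conventionally reported in kDa to one
#' decimal.
#'
#' @param protein Protein string over the 20 standard one-letter codes
#'   (case-insensitive).
#' @return Mass in daltons.
#' @examples
#' average_molecular_mass("G")  # 75.0672
#' @export
average_molecular_mass <- function(protein) {
  stopifnot(is.character(protein), length(protein) == 1L)
  aa <- strsplit(toupper(protein), "")[[1]]
  if (length(aa) == 0)
    stop("sequence error: empty protein sequence", call. = FALSE)
  if (any(!aa %in% names(.residue_mass)))
    stop("sequence error: unknown residue(s): ",
         paste(unique(aa[!aa %in% names(.residue_mass)]), collapse = ", "),
         call. = FALSE)
  sum(.residue_mass[aa]) + .water_mass
}

#' Read sequences from a FASTA file
#'
#' Minimal single-/multi-record FASTA reader returning plain strings.
#'
#' @param path FASTA file path.
#' @return Named character vector (names from the header lines up to the
#'   first whitespace).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("cannot read FASTA: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grepl("^>", lines)
  if (!length(lines) || !hdr[1])
    stop("malformed FASTA (no header): ", path, call. = FALSE)
  idx <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], idx[!hdr]),
                 function(x) gsub("[ \t]", "", paste(x, collapse = "")), "")
  names(seqs) <- sub("^>\\s*(\\S+).*$", "\\1", lines[hdr])[as.integer(names(seqs))]
  seqs
}

#' Fetch a nucleotide accession from NCBI as FASTA (requires network)
#'
#' Convenience downloader for reproducing reported sequence statistics from
#' a GenBank accession. Not used by any test; offline sessions should
#' supply a local FASTA instead.
#'
#' @param accession GenBank accession, e.g. `"PP171485"`.
#' @param dest Destination file path.
#' @return `dest`, invisibly.
#' @export
fetch_ncbi_fasta <- function(accession, dest = paste0(accession, ".fasta")) {
  url <- paste0("https://eutils.ncbi.nlm.nih.gov/entrez/eutils/efetch.fcgi",
                "?db=nuccore&id=", accession, "&rettype=fasta&retmode=text")
  utils::download.file(url, dest, quiet = TRUE)
  invisible(dest)
}

#' Length and mass statistics for ORF sequences
#'
#' One-stop summary used by the command-line `seqstats` mode: for each ORF,
#' its length, the encoded protein length, and the protein's average
#' molecular mass.
#'
#' @param seqs Named character vector of ORF nucleotide sequences (e.g. from
#'   [read_fasta()]).
#' @return Data frame: `name`, `orf_bp`, `protein_aa`, `mass_da`,
#'   `mass_kda` (one decimal).
#' @export
seq_stats <- function(seqs) {
  stopifnot(is.character(seqs), length(seqs) >= 1)
  if (is.null(names(seqs))) names(seqs) <- sprintf("seq%d", seq_along(seqs))
  rows <- lapply(names(seqs), function(nm) {
    prot <- translate_orf(seqs[[nm]])
    mass <- average_molecular_mass(prot)
    data.frame(name = nm, orf_bp = nchar(.clean_orf(seqs[[nm]])),
               protein_aa = nchar(prot), mass_da = mass,
               mass_kda = .round_half_up(mass / 1000, 1),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
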