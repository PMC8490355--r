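# Monoisotopic and average residue masses (Da) for the 20 canonical amino
# acids; water is added once per peptide. Values to 5 decimals.
MONO_RESIDUE <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)
AVG_RESIDUE <- c(
  G = 57.05190, A = 71.07880, S = 87.07820, P = 97.11670, V = 99.13260,
  T = 101.10510, C = 103.13880, L = 113.15940, I = 113.15940, N = 114.10380,
  D = 115.08860, Q = 128.13070, K = 128.17410, E = 129.11550, M = 131.19260,
  H = 137.14110, F = 147.17660, R = 156.18750, Y = 163.17600, W = 186.21320
)
WATER_MONO <- 18.01056
WATER_AVG <- 18.01528

check_canonical <- function(sequence) {
  ch <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- which(!ch %in% names(MONO_RESIDUE))
  if (length(bad) > 0L) {
    rlang::abort(sprintf(
      "non-canonical residue '%s' at position %d", ch[bad[1]], bad[1]
    ))
  }
  ch
}

#' Tryptic cleavage of a protein sequence
#'
#' Cleaves after every lysine (K) or arginine (R) unless the next residue is
#' proline (P), the standard trypsin specificity. The returned fragments
#' partition the input: concatenating them in order reproduces the sequence
#' exactly.
#'
#' @param sequence Protein sequence, 1-letter uppercase canonical amino
#'   acids.
#' @return A tibble with one row per fragment: `sequence`, `start` (0-based
#'   position in the parent), `end` (exclusive).
#' @examples
#' cleave("HGLDNYRTPGSR")
#' @export
cleave <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  ch <- check_canonical(sequence)
  n <- length(ch)
  cut_after <- ch %in% c("K", "R") & c(ch[-1] != "P", TRUE)
  ends <- which(cut_after)
  if (length(ends) == 0L || ends[length(ends)] != n) ends <- c(ends, n)
  starts <- c(0L, ends[-length(ends)])
  tibble::tibble(
    sequence = substring(sequence, starts + 1L, ends),
    start = starts,
    end = as.integer(ends)
  )
}

#' Monoisotopic (or average) peptide mass with cysteine alkylation
#'
#' Mass is the sum of residue masses plus one water, plus
#' `alkylation_shift` Da for every cysteine. The default shift of 57.02 Da
#' is the carbamidomethylation added by iodoacetamide treatment; set it to 0
#' for unmodified cysteines.
#'
#' @param sequence Character vector of peptide sequences.
#' @param alkylation_shift Mass added per cysteine, Da. Default 57.02.
#' @param monoisotopic Use monoisotopic residue masses (default) or average.
#' @return Numeric vector of masses in Da.
#' @examples
#' peptide_mass("HGLDNYR")
#' peptide_mass("CELAAMK", alkylation_shift = 57.02)
#' @export
peptide_mass <- function(sequence, alkylation_shift = 57.02,
                         monoisotopic = TRUE) {
  tab <- if (monoisotopic) MONO_RESIDUE else AVG_RESIDUE
  water <- if (monoisotopic) WATER_MONO else WATER_AVG
  vapply(sequence, function(s) {
    ch <- check_canonical(s)
    sum(tab[ch]) + water + sum(ch == "C") * alkylation_shift
  }, numeric(1), USE.NAMES = FALSE)
}

#' Digestion parameter set
#'
#' Peptides outside the mass window are excluded because the nanopore does
#' not resolve them: the working window is 500-1700 Da, bounds inclusive.
#' `missed_cleavages > 0` additionally reports fragments joined across up to
#' that many skipped cleavage sites, emulating incomplete hydrolysis.
#'
#' @param min_mass,max_mass Mass window in Da, inclusive.
#' @param alkylation_shift Fixed cysteine modification, Da.
#' @param missed_cleavages Non-negative integer.
#' @param monoisotopic Residue mass table flag, see [peptide_mass()].
#' @return A list of class `digest_params`.
#' @export
digest_params <- function(min_mass = 500, max_mass = 1700,
                          alkylation_shift = 57.02, missed_cleavages = 0L,
                          monoisotopic = TRUE) {
  if (!(min_mass > 0 && min_mass < max_mass)) {
    rlang::abort("require 0 < min_mass < max_mass")
  }
  if (missed_cleavages < 0) rlang::abort("missed_cleavages must be >= 0")
  structure(
    list(
      min_mass = min_mass, max_mass = max_mass,
      alkylation_shift = alkylation_shift,
      missed_cleavages = as.integer(missed_cleavages),
      monoisotopic = isTRUE(monoisotopic)
    ),
    class = "digest_params"
  )
}

#' In-silico tryptic digest of a protein
#'
#' Applies [cleave()], optionally expands missed-cleavage products, computes
#' each peptide's mass via [peptide_mass()], and retains peptides inside the
#' mass window of `params` (bounds inclusive).
#'
#' @param sequence Protein sequence string (mature chain, 1-letter code).
#' @param params A [digest_params()] object.
#' @param parent_id Identifier stored with each peptide.
#' @return A tibble: `parent_id`, `start`, `sequence`, `n_cys`, `mass`,
#'   `missed` (number of internal skipped cleavage sites).
#' @examples
#' digest_protein("HGLDNYRTPGSR", digest_params())
#' @export
digest_protein <- function(sequence, params = digest_params(),
                           parent_id = NA_character_) {
  stopifnot(inherits(params, "digest_params"))
  frags <- cleave(sequence)
  k <- params$missed_cleavages
  pieces <- purrr::map_dfr(0:k, function(m) {
    n <- nrow(frags)
    if (n - m <= 0) return(NULL)
    i <- seq_len(n - m)
    tibble::tibble(
      start = frags$start[i],
      sequence = vapply(i, function(j) {
        paste0(frags$sequence[j:(j + m)], collapse = "")
      }, character(1)),
      missed = m
    )
  })
  pieces$n_cys <- vapply(
    strsplit(pieces$sequence, "", fixed = TRUE),
    function(ch) sum(ch == "C"), integer(1)
  )
  pieces$mass <- peptide_mass(
    pieces$sequence,
    alkylation_shift = params$alkylation_shift,
    monoisotopic = params$monoisotopic
  )
  pieces$parent_id <- parent_id
  out <- dplyr::filter(
    pieces, .data$mass >= params$min_mass, .data$mass <= params$max_mass
  )
  dplyr::select(
    out, "parent_id", "start", "sequence", "n_cys", "mass", "missed"
  )
}

#' Digest every record of a FASTA file or protein table
#'
#' @param proteins Either a path to a FASTA file or a tibble with columns
#'   `id` and `sequence`.
#' @param params A [digest_params()] object.
#' @return Row-bound [digest_protein()] tibbles, `parent_id` set to each
#'   record id.
#' @export
digest_fasta <- function(proteins, params = digest_params()) {
  tbl <- if (is.character(proteins)) read_fasta(proteins) else proteins
  stopifnot(all(c("id", "sequence") %in% names(tbl)))
  purrr::map2_dfr(tbl$sequence, tbl$id, function(s, id) {
    digest_protein(s, params, parent_id = id)
  })
}

#' Read a multi-record protein FASTA file
#'
#' Uses Biostrings when available; otherwise falls back to a minimal
#' plain-text parser sufficient for uncompressed amino-acid FASTA.
#'
#' @param path FASTA file path.
#' @return A tibble with columns `id` (first word of the header) and
#'   `sequence`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) rlang::abort(sprintf("FASTA file not found: %s", path))
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    aa <- Biostrings::readAAStringSet(path)
    return(tibble::tibble(
      id = vapply(strsplit(names(aa), "\\s+"), `[[`, "", 1L),
      sequence = as.character(aa)
    ))
  }
  lines <- readr::read_lines(path)
  hdr <- which(startsWith(lines, ">"))
  if (length(hdr) == 0L) rlang::abort(sprintf("no FASTA records in %s", path))
  ends <- c(hdr[-1] - 1L, length(lines))
  tibble::tibble(
    id = vapply(strsplit(sub("^>", "", lines[hdr]), "\\s+"), `[[`, "", 1L),
    sequence = vapply(seq_along(hdr), function(i) {
      paste0(toupper(trimws(lines[(hdr[i] + 1L):ends[i]])), collapse = "")
    }, character(1))
  )
}
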