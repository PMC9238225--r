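# Protein refractive index increment (dn/dc) from amino-acid composition.
#
# A protein's dn/dc (mL/g) measures how much it raises the refractive index
# of a solution per unit concentration; for lens crystallins it governs
# their contribution to the focusing power of the lens. Following the
# composition-based computational approach of Zhao, Brown & Schuck (2011),
# each residue contributes a specific refraction (via the Lorentz-Lorenz
# relation) and a partial specific volume; mass-fraction averaging gives the
# protein refractive index, and the Heller equation converts it to dn/dc in
# a solvent of known refractive index. Residue-level data (McMeekin
# refractivities, Cohn-Edsall volumes) ship as a plain-text table.

.DNDC_REF_SOLVENT <- 1.3340  # solvent refractive index the residue table refers to

#' Residue refractivity table
#'
#' Per-residue data used by [protein_dndc()]: average residue mass (free
#' amino acid minus one water, g/mol), Cohn-Edsall partial specific volume
#' (mL/g), and the residue-level refractive index increment at 589 nm and
#' 25 C in water (mL/g).
#'
#' @return A data frame keyed by one-letter residue code.
#' @references Zhao H, Brown PH, Schuck P (2011). On the distribution of
#'   protein refractive index increments. Biophys J 100:2309-2317.
#'   McMeekin TL, Wilensky M, Groves ML (1964). Refractive indices of
#'   proteins in relation to amino acid composition and specific volume.
#'   Biochem Biophys Res Commun 7:151-156.
#' @export
residue_refractivity <- function() {
  if (is.null(.visadapt_cache$residue_tab)) {
    tab <- utils::read.delim(extdata_path("residue_refractivity.tsv"),
                             comment.char = "#", stringsAsFactors = FALSE)
    rownames(tab) <- tab$residue
    .visadapt_cache$residue_tab <- tab
  }
  .visadapt_cache$residue_tab
}

.STANDARD_RESIDUES <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I",
                        "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Read protein sequences from a FASTA file
#'
#' Sequences are uppercased and sanitized: non-standard residues (X, B, Z,
#' U, O, stop `*`, gap characters) are removed and counted per record.
#'
#' @param path Path to a protein FASTA file.
#' @param quiet Suppress the per-record message about dropped residues.
#' @return A data frame with columns `id`, `sequence`, `n_dropped`.
#' @export
parse_fasta <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  aa <- Biostrings::readAAStringSet(path)
  if (!length(aa)) stop("no records in FASTA file: ", path, call. = FALSE)
  ids <- vapply(strsplit(names(aa), "[[:space:]]+"), `[[`, "", 1L)
  raw <- toupper(as.character(aa))
  clean <- gsub(sprintf("[^%s]", paste(.STANDARD_RESIDUES, collapse = "")),
                "", raw)
  dropped <- nchar(raw) - nchar(clean)
  if (!quiet && any(dropped > 0)) {
    for (i in which(dropped > 0)) {
      message(sprintf("parse_fasta: dropped %d non-standard residue(s) from %s",
                      dropped[i], ids[i]))
    }
  }
  if (any(!nzchar(clean))) {
    stop("record(s) empty after sanitization: ",
         paste(ids[!nzchar(clean)], collapse = ", "), call. = FALSE)
  }
  data.frame(id = ids, sequence = clean, n_dropped = dropped,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Amino-acid composition of a protein sequence
#'
#' @param sequence A sanitized amino-acid string (standard 20 letters).
#' @return A named integer vector of residue counts over all 20 residues
#'   (zeros included); counts sum to the sequence length.
#' @export
residue_composition <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L,
            nzchar(sequence))
  chars <- strsplit(toupper(sequence), "")[[1]]
  bad <- setdiff(unique(chars), .STANDARD_RESIDUES)
  if (length(bad)) {
    stop("non-standard residues in sequence: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  counts <- table(factor(chars, levels = .STANDARD_RESIDUES))
  stats::setNames(as.integer(counts), .STANDARD_RESIDUES)
}

# Lorentz-Lorenz ratio (n^2-1)/(n^2+2) and its inverse.
.ll <- function(n) (n^2 - 1) / (n^2 + 2)
.ll_inv <- function(q) sqrt((1 + 2 * q) / (1 - q))

# Residue refractive index implied by the table's residue dn/dc and volume,
# inverting the Heller relation at the table's reference solvent.
.residue_n <- function(tab) {
  k <- 2 * tab$dndc / (3 * .DNDC_REF_SOLVENT * tab$vbar)
  .DNDC_REF_SOLVENT * .ll_inv(k)
}

#' Protein refractive index increment from composition
#'
#' Computes dn/dc (mL/g) for a protein under 589 nm light at 25 C. Residue
#' specific refractions and partial specific volumes are mass-fraction
#' averaged over the composition, the protein refractive index follows from
#' the Lorentz-Lorenz relation, and the Heller equation gives dn/dc in the
#' stated solvent. The result depends only on composition, not residue
#' order.
#'
#' @param x A sequence string, or a named residue count vector as returned
#'   by [residue_composition()].
#' @param solvent_n Solvent refractive index (default 1.3340, dilute
#'   aqueous buffer at 589 nm and 25 C).
#' @param table Residue data table, see [residue_refractivity()].
#' @return An object of class `"dndc_result"`: `dndc` (mL/g), `conditions`
#'   (wavelength 589 nm, temperature 25 C, `solvent_n`), `mass` (g/mol).
#' @export
protein_dndc <- function(x, solvent_n = 1.3340,
                         table = residue_refractivity()) {
  if (is.character(x)) x <- residue_composition(x)
  stopifnot(is.numeric(x), !is.null(names(x)))
  x <- x[x > 0]
  if (!length(x)) stop("empty composition", call. = FALSE)
  missing <- setdiff(names(x), rownames(table))
  if (length(missing)) {
    stop("residue(s) missing from refractivity table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  stopifnot_scalar_number(solvent_n, "solvent_n", 1, 2)
  tab <- table[names(x), , drop = FALSE]
  mass_i <- x * tab$mass_residue
  w <- mass_i / sum(mass_i)                   # residue mass fractions
  n_i <- .residue_n(tab)
  r_i <- tab$vbar * .ll(n_i)                  # residue specific refractions
  vbar <- sum(w * tab$vbar)
  rbar <- sum(w * r_i)
  n_protein <- .ll_inv(rbar / vbar)
  m <- n_protein / solvent_n
  dndc <- 1.5 * solvent_n * vbar * (m^2 - 1) / (m^2 + 2)
  structure(
    list(dndc = dndc,
         conditions = list(wavelength_nm = 589, temperature_c = 25,
                           solvent_n = solvent_n),
         mass = sum(mass_i),
         n_protein = n_protein),
    class = "dndc_result"
  )
}

#' @export
print.dndc_result <- function(x, ...) {
  cat(sprintf(
    "dn/dc = %.4f mL/g (589 nm, 25 C, solvent n = %.4f; protein mass %.1f g/mol)\n",
    x$dndc, x$conditions$solvent_n, x$mass))
  invisible(x)
}

#' dn/dc for a table of proteins
#'
#' @param records A data frame with columns `id` and `sequence` (e.g. from
#'   [parse_fasta()]).
#' @param classes Optional named character vector or data frame
#'   (`id`, `crystallin_class`) assigning each protein a crystallin class.
#' @param ... Passed to [protein_dndc()].
#' @return A data frame: `id`, `crystallin_class` (or `NA`), `dndc`.
#' @export
dndc_table <- function(records, classes = NULL, ...) {
  stopifnot(is.data.frame(records),
            all(c("id", "sequence") %in% names(records)))
  cls <- rep(NA_character_, nrow(records))
  if (!is.null(classes)) {
    if (is.data.frame(classes)) {
      classes <- stats::setNames(classes$crystallin_class, classes$id)
    }
    cls <- unname(classes[records$id])
  }
  data.frame(
    id = records$id,
    crystallin_class = cls,
    dndc = vapply(records$sequence,
                  function(s) protein_dndc(s, ...)$dndc, 0),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Unweighted per-class mean dn/dc
#'
#' @param results A data frame with columns `crystallin_class` and `dndc`
#'   (e.g. from [dndc_table()]). Rows with `NA` class are dropped with a
#'   warning.
#' @return A data frame: `crystallin_class`, `n`, `mean_dndc`.
#' @export
class_mean_dndc <- function(results) {
  stopifnot(is.data.frame(results),
            all(c("crystallin_class", "dndc") %in% names(results)))
  drop <- is.na(results$crystallin_class)
  if (any(drop)) {
    warning(sum(drop), " protein(s) without a class were omitted")
    results <- results[!drop, , drop = FALSE]
  }
  if (!nrow(results)) stop("no classified proteins", call. = FALSE)
  agg <- split(results$dndc, results$crystallin_class)
  data.frame(crystallin_class = names(agg),
             n = lengths(agg),
             mean_dndc = vapply(agg, mean, 0),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Expression-weighted mean dn/dc
#'
#' Weighted mean of per-protein dn/dc values with nonnegative expression
#' weights (e.g. TMM-normalized expression summed over samples of a life
#' stage). Invariant to rescaling all weights by a positive constant.
#'
#' @param dndc Numeric vector of dn/dc values.
#' @param weights Nonnegative weights, same length, with a positive sum.
#' @return The weighted mean (mL/g).
#' @export
weighted_mean_dndc <- function(dndc, weights) {
  stopifnot(is.numeric(dndc), is.numeric(weights),
            length(dndc) == length(weights))
  if (any(weights < 0) || anyNA(weights)) {
    stop("weights must be nonnegative", call. = FALSE)
  }
  if (sum(weights) <= 0) stop("weights must not all be zero", call. = FALSE)
  sum(weights * dndc) / sum(weights)
}
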