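STUDY_GROUPS <- c("RFposCCPpos_RA", "RFnegCCPpos_RA", "RFnegCCPneg_RA",
                  "RFneg_control", "RFpos_control")

# monoisotopic residue masses (Da); X treated as averagine-like placeholder
AA_MONO <- c(A = 71.03711, R = 156.10111, N = 114.04293, D = 115.02694,
             C = 103.00919, E = 129.04259, Q = 128.05858, G = 57.02146,
             H = 137.05891, I = 113.08406, L = 113.08406, K = 128.09496,
             M = 131.04049, F = 147.06841, P = 97.05276, S = 87.03203,
             T = 101.04768, W = 186.07931, Y = 163.06333, V = 99.06841,
             X = 111.0)
PROTON <- 1.007276
WATER <- 18.010565

#' Peptide m/z from sequence and charge
#'
#' Monoisotopic peptide mass (sum of residue masses plus water) converted
#' to m/z for a given positive charge.
#'
#' @param sequence Amino-acid string(s).
#' @param charge Positive integer charge(s).
#' @return Numeric m/z values (Th).
#' @export
peptideMz <- function(sequence, charge = 2L) {
  mass <- vapply(strsplit(toupper(sequence), ""), function(ch) {
    if (!all(ch %in% names(AA_MONO)))
      stop("validation error: non-amino-acid characters in '",
           paste(ch, collapse = ""), "'")
    sum(AA_MONO[ch]) + WATER
  }, numeric(1))
  (mass + charge * PROTON) / charge
}

#' Synthetic cohort design
#'
#' Parameters of a simulated affinity-enrichment LC-MS/MS experiment.
#' The default cohort reproduces the five-group structure of an 86-sample
#' rheumatoid-factor study (27 RF+/CCP+ RA, 5 RF-/CCP+ RA, 22 RF-/CCP- RA,
#' 28 RF- disease controls, 4 RF+ disease controls).
#'
#' @param groupSizes Named integer vector of samples per group.
#' @param nBackgroundPeptides Number of non-immunoglobulin features.
#' @param nIgPeptides Number of germline-derived features (constant- and
#'   variable-region peptides obtained by in-silico Lys-C/chymotrypsin
#'   digestion).
#' @param nUpregulated Number of variable-region peptides carrying a
#'   group effect.
#' @param foldChange True abundance multiplier of upregulated peptides in
#'   the effect groups (default 8).
#' @param noiseCV Within-group coefficient of variation of the log-normal
#'   abundance noise (default 0.3).
#' @param missingRateLowAbundance Probability that a low-abundance value
#'   (bottom quintile) is censored to missing.
#' @param effectGroups Groups in which upregulated peptides are elevated
#'   (default the two RF-positive groups).
#' @param fracAlsoSeronegative Fraction of upregulated peptides that are
#'   additionally elevated in RF-/CCP- RA.
#' @param fracCdrVariant Fraction of variable-region peptides carrying
#'   1-3 point substitutions inside a CDR (these fall outside the search
#'   database and are identifiable only de novo).
#' @param fracUnsequenced Fraction of features left with no
#'   identification.
#' @param igConstantEffect If TRUE, all constant-region peptides carry
#'   the fold-change multiplier in the effect groups as well, modelling
#'   elevated circulating RF titres raising every RF-derived peptide;
#'   this is the condition isotype positivity calling is studied under.
#'   Default FALSE: when ~40% of all features are elevated, the
#'   reference normalization (whose model assumes most features
#'   unchanged) absorbs roughly half of the true fold change, so the
#'   default cohort plants effects only on the designated variable-region
#'   subset.
#' @param scaleFactorRange Range of per-sample global intensity factors
#'   (log-uniform), exercising normalization.
#' @param seed Integer seed; the whole simulation is reproducible.
#' @return A list of class `CohortDesign`.
#' @export
cohortDesign <- function(groupSizes = c(RFposCCPpos_RA = 27L,
                                        RFnegCCPpos_RA = 5L,
                                        RFnegCCPneg_RA = 22L,
                                        RFneg_control = 28L,
                                        RFpos_control = 4L),
                         nBackgroundPeptides = 120L, nIgPeptides = 80L,
                         nUpregulated = 25L, foldChange = 8,
                         noiseCV = 0.3, missingRateLowAbundance = 0.2,
                         effectGroups = c("RFposCCPpos_RA",
                                          "RFpos_control"),
                         fracAlsoSeronegative = 0.3,
                         fracCdrVariant = 0.25, fracUnsequenced = 0.1,
                         igConstantEffect = FALSE,
                         scaleFactorRange = c(0.5, 2), seed = 1L) {
  stopifnot(all(groupSizes >= 0), foldChange > 0, noiseCV >= 0,
            nBackgroundPeptides >= 0, nIgPeptides >= 0, nUpregulated >= 0,
            missingRateLowAbundance >= 0, missingRateLowAbundance <= 1,
            fracAlsoSeronegative >= 0, fracAlsoSeronegative <= 1,
            fracCdrVariant >= 0, fracCdrVariant <= 1,
            fracUnsequenced >= 0, fracUnsequenced <= 1,
            all(effectGroups %in% names(groupSizes)))
  structure(list(groupSizes = groupSizes,
                 nBackgroundPeptides = as.integer(nBackgroundPeptides),
                 nIgPeptides = as.integer(nIgPeptides),
                 nUpregulated = as.integer(nUpregulated),
                 foldChange = foldChange, noiseCV = noiseCV,
                 missingRateLowAbundance = missingRateLowAbundance,
                 effectGroups = effectGroups,
                 fracAlsoSeronegative = fracAlsoSeronegative,
                 fracCdrVariant = fracCdrVariant,
                 fracUnsequenced = fracUnsequenced,
                 igConstantEffect = isTRUE(igConstantEffect),
                 scaleFactorRange = scaleFactorRange,
                 seed = as.integer(seed)),
            class = "CohortDesign")
}

# digest every germline of the requested segments, tracking origin and,
# for V peptides, the IMGT positions the peptide covers
.digestGermlines <- function(germlines, segments) {
  keep <- which(segmentType(germlines) %in% segments)
  out <- list()
  for (i in keep) {
    gene <- germlineNames(germlines)[i]
    seq <- as.character(germlineSequences(germlines)[[i]])
    pos <- imgtPositions(germlines)[[i]]
    for (pep in digestSequence(seq, maxMissedCleavages = 1L)) {
      st <- as.integer(regexpr(pep, seq, fixed = TRUE))
      ncdr <- 0L
      if (!is.null(pos) && st > 0) {
        regs <- regionAtPosition(pos[st:(st + nchar(pep) - 1L)])
        ncdr <- sum(grepl("^CDR", regs), na.rm = TRUE)
      }
      out[[length(out) + 1L]] <- data.frame(
        sequence = pep, gene = gene,
        segment = segmentType(germlines)[i],
        isotype = isotypeGroup(germlines)[i],
        n_cdr = ncdr, stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, out)
  df[!duplicated(df$sequence), , drop = FALSE]
}

.mutateCdr <- function(sequence, gene, germlines) {
  # substitute 1-3 residues inside the CDR span of a V-derived peptide
  i <- match(gene, germlineNames(germlines))
  seq <- as.character(germlineSequences(germlines)[[i]])
  pos <- imgtPositions(germlines)[[i]]
  st <- as.integer(regexpr(sequence, seq, fixed = TRUE))
  regs <- regionAtPosition(pos[st:(st + nchar(sequence) - 1L)])
  cdr_idx <- which(grepl("^CDR", regs))
  if (!length(cdr_idx)) return(sequence)
  k <- min(sample(1:3, 1), length(cdr_idx))
  aa <- setdiff(names(AA_MONO), "X")
  for (p in sample(cdr_idx, k)) {
    old <- substr(sequence, p, p)
    substr(sequence, p, p) <- sample(setdiff(aa, old), 1)
  }
  sequence
}

#' Simulate a complete synthetic experiment
#'
#' Generates a cohort with the study's group structure, an LC-MS feature
#' table with log-normal abundances (group-specific fold-change effects on
#' designated variable-region peptides, per-sample global scale factors,
#' abundance-dependent missingness), and a matched identification table
#' (database-search scores for database peptides, ALC% de novo scores for
#' CDR-mutated peptides, a fraction left unsequenced), together with the
#' generating ground truth.
#'
#' @param design A [cohortDesign()].
#' @param germlines A [GermlineSet] supplying immunoglobulin peptides.
#' @param experimentId Label stored in the sample metadata.
#' @return A list with elements `features` (data.frame: feature_id, mz,
#'   charge, rt, has_msms, sequence), `abundance` (features x samples
#'   matrix, `NA` = missing), `idents` (data.frame), `samples`
#'   (data.frame: sample_id, group, experiment_id), `truth` (data.frame
#'   with per-feature source, region class, isotype, upregulation flags
#'   and true multiplier) and `sampleScale` (true per-sample factors).
#'   The same design (including seed) always yields identical output.
#' @examples
#' sim <- simulateExperiment(cohortDesign(groupSizes = c(
#'   RFposCCPpos_RA = 4L, RFnegCCPpos_RA = 2L, RFnegCCPneg_RA = 3L,
#'   RFneg_control = 4L, RFpos_control = 2L), nBackgroundPeptides = 20L,
#'   nIgPeptides = 15L, nUpregulated = 5L))
#' dim(sim$abundance)
#' @export
simulateExperiment <- function(design, germlines = loadGermlineSet(),
                               experimentId = "main") {
  stopifnot(inherits(design, "CohortDesign"))
  if (design$nIgPeptides > 0 && length(germlines) == 0)
    stop("configuration error: empty germline set with nIgPeptides > 0")
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(design$seed)

  ## samples -----------------------------------------------------------
  groups <- rep(names(design$groupSizes), design$groupSizes)
  nS <- length(groups)
  samples <- data.frame(
    sample_id = sprintf("%s_S%03d", experimentId, seq_len(nS)),
    group = groups, experiment_id = experimentId,
    stringsAsFactors = FALSE)

  ## peptide universe --------------------------------------------------
  pool <- .digestGermlines(germlines, c("V", "constant"))
  vpool <- pool[pool$segment == "V", ]
  cpool <- pool[pool$segment == "constant", ]
  nC <- min(floor(design$nIgPeptides / 2), nrow(cpool))
  nV <- min(design$nIgPeptides - nC, nrow(vpool))
  ig <- rbind(
    if (nC > 0) cpool[sample(nrow(cpool), nC), ] else NULL,
    if (nV > 0) vpool[sample(nrow(vpool), nV), ] else NULL)

  aa <- setdiff(names(AA_MONO), "X")
  bg <- data.frame(
    sequence = vapply(seq_len(design$nBackgroundPeptides), function(i)
      paste(sample(aa, sample(7:18, 1), replace = TRUE), collapse = ""),
      character(1)),
    gene = NA_character_, segment = "background",
    isotype = NA_character_, n_cdr = 0L, stringsAsFactors = FALSE)

  pep <- rbind(ig, bg)
  pep <- pep[!duplicated(pep$sequence), ]
  nP <- nrow(pep)

  ## ground-truth effects ----------------------------------------------
  v_idx <- which(pep$segment == "V")
  up_v <- if (design$nUpregulated > 0 && length(v_idx) > 0)
    sample(v_idx, min(design$nUpregulated, length(v_idx))) else integer()
  up_idx <- if (design$igConstantEffect)
    c(up_v, which(pep$segment == "constant")) else up_v
  also_sn <- up_v[seq_len(round(design$fracAlsoSeronegative *
                                length(up_v)))]
  # CDR point variants: only V peptides that genuinely cover >=3 CDR
  # residues, so the mutated sequence is de-novo-only and CDR-labelled
  cdr_candidates <- setdiff(which(pep$segment == "V" & pep$n_cdr >= 3),
                            integer(0))
  n_var <- round(design$fracCdrVariant * length(cdr_candidates))
  var_idx <- if (n_var > 0) sample(cdr_candidates, n_var) else integer()
  db_seq <- pep$sequence
  for (i in var_idx)
    pep$sequence[i] <- .mutateCdr(pep$sequence[i], pep$gene[i], germlines)

  mult <- matrix(1, nP, nS)
  eff_cols <- samples$group %in% design$effectGroups
  sn_cols <- samples$group == "RFnegCCPneg_RA"
  mult[up_idx, eff_cols] <- design$foldChange
  if (length(also_sn)) mult[also_sn, sn_cols] <- design$foldChange

  ## abundances --------------------------------------------------------
  base <- exp(stats::rnorm(nP, log(1e6), 1))
  sdlog <- sqrt(log(1 + design$noiseCV^2))
  scale <- exp(stats::runif(nS, log(design$scaleFactorRange[1]),
                            log(design$scaleFactorRange[2])))
  ab <- base * mult *
    exp(matrix(stats::rnorm(nP * nS, -sdlog^2 / 2, sdlog), nP, nS))
  ab <- sweep(ab, 2, scale, "*")
  low <- ab < stats::quantile(ab, 0.2)
  cens <- low & matrix(stats::runif(nP * nS), nP, nS) <
    design$missingRateLowAbundance
  ab[cens] <- NA_real_
  dimnames(ab) <- list(sprintf("%s_F%04d", experimentId, seq_len(nP)),
                       samples$sample_id)

  ## features + identifications ----------------------------------------
  charge <- sample(2:4, nP, replace = TRUE,
                   prob = c(0.55, 0.35, 0.10))
  features <- data.frame(
    feature_id = rownames(ab),
    mz = round(peptideMz(pep$sequence, charge), 4),
    charge = charge,
    rt = round(stats::runif(nP, 5, 60), 2),
    has_msms = stats::runif(nP) < 0.92,
    sequence = NA_character_, stringsAsFactors = FALSE)

  unseq <- stats::runif(nP) < design$fracUnsequenced
  is_var <- seq_len(nP) %in% var_idx
  idents <- list()
  for (i in seq_len(nP)) {
    if (unseq[i]) next
    if (is_var[i]) {
      alc <- if (stats::runif(1) < 0.9) stats::runif(1, 81, 99)
             else stats::runif(1, 50, 80)
      idents[[length(idents) + 1L]] <- data.frame(
        feature_id = features$feature_id[i], sequence = pep$sequence[i],
        engine = "de_novo", score = NA_real_, alc = round(alc, 1),
        protein_accessions = "", stringsAsFactors = FALSE)
    } else {
      score <- pmax(10, pmin(120, stats::rnorm(1, 60, 18)))
      idents[[length(idents) + 1L]] <- data.frame(
        feature_id = features$feature_id[i], sequence = pep$sequence[i],
        engine = "database_search", score = round(score, 1),
        alc = NA_real_,
        protein_accessions = if (is.na(pep$gene[i])) "" else pep$gene[i],
        stringsAsFactors = FALSE)
      if (score >= 30) features$sequence[i] <- pep$sequence[i]
    }
  }
  idents <- do.call(rbind, idents)

  truth <- data.frame(
    feature_id = features$feature_id,
    sequence = pep$sequence, db_sequence = db_seq,
    source = pep$segment, gene = pep$gene, isotype = pep$isotype,
    n_cdr = pep$n_cdr, cdr_variant = is_var,
    upregulated = seq_len(nP) %in% up_idx,
    also_seronegative = seq_len(nP) %in% also_sn,
    multiplier = ifelse(seq_len(nP) %in% up_idx, design$foldChange, 1),
    stringsAsFactors = FALSE)

  list(features = features, abundance = ab, idents = idents,
       samples = samples, truth = truth,
       sampleScale = stats::setNames(scale, samples$sample_id))
}
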