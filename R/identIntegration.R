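#' Filter de novo identifications
#'
#' Retains de novo records with ALC% strictly greater than the threshold
#' and a sequence of at least `minLength` residues.
#'
#' @param idents Identification data.frame (see [readIdentTable()]).
#' @param alcMin ALC% threshold (strict `>`, default 80).
#' @param minLength Minimum sequence length (default 3).
#' @return The filtered data.frame (de novo rows only).
#' @export
filterDeNovo <- function(idents, alcMin = 80, minLength = 3L) {
  dn <- idents[idents$engine == "de_novo", , drop = FALSE]
  dn[!is.na(dn$alc) & dn$alc > alcMin & nchar(dn$sequence) >= minLength, ,
     drop = FALSE]
}

#' Remove confidently Ig-identified features from the de novo pool
#'
#' Features whose database-search identification is Ig-related with a
#' score at or above the threshold are already explained by the database
#' and are excluded from further de novo sequencing.
#'
#' @param deNovoIdents De novo identification data.frame.
#' @param dbIdents Database-search identification data.frame.
#' @param igRelated Logical vector parallel to `dbIdents` rows: whether
#'   the database-search sequence is immunoglobulin-related (from
#'   [annotatePeptides()]).
#' @param mascotMin Score threshold (inclusive `>=`, default 30).
#' @return `deNovoIdents` without the excluded features.
#' @export
excludeIgMascotFromDeNovo <- function(deNovoIdents, dbIdents, igRelated,
                                      mascotMin = 30) {
  stopifnot(length(igRelated) == nrow(dbIdents))
  drop <- dbIdents$feature_id[igRelated & !is.na(dbIdents$score) &
                              dbIdents$score >= mascotMin]
  deNovoIdents[!deNovoIdents$feature_id %in% drop, , drop = FALSE]
}

#' Resolve database-search and de novo identifications per feature
#'
#' Applies the priority rule: a database-search identification with score
#' `>= mascotMin` wins; otherwise a passing de novo identification is
#' retained; a sub-threshold database-search hit with no de novo
#' alternative is retained but flagged low-confidence; features with no
#' identification are `unidentified`.  Ties among several passing de novo
#' candidates for one feature are broken by highest ALC, then longest
#' sequence, then lexicographic order.
#'
#' @param featureIds Character vector: the complete feature universe;
#'   every id appears exactly once in the output.
#' @param dbIdents Database-search identification data.frame.
#' @param deNovoIdents De novo identification data.frame, already passed
#'   through [filterDeNovo()] (re-filtered here defensively).
#' @param mascotMin Database-search priority threshold (default 30).
#' @param alcMin,minLength De novo filter parameters.
#' @param ambiguity How to treat two database-search records for one
#'   feature: `"error"` (default) or `"highest"` (highest score wins,
#'   with a message).
#' @return data.frame with one row per feature: `feature_id`, `sequence`,
#'   `provenance` (`database_search`/`de_novo`/`unidentified`), `score`,
#'   `alc`, `low_confidence`.
#' @export
resolveIdentifications <- function(featureIds, dbIdents, deNovoIdents,
                                   mascotMin = 30, alcMin = 80,
                                   minLength = 3L,
                                   ambiguity = c("error", "highest")) {
  ambiguity <- match.arg(ambiguity)
  db <- dbIdents[dbIdents$engine == "database_search", , drop = FALSE]
  if (anyDuplicated(db$feature_id)) {
    if (ambiguity == "error")
      stop("ambiguity error: multiple database-search records for ",
           "feature(s) ",
           paste(unique(db$feature_id[duplicated(db$feature_id)]),
                 collapse = ", "))
    message("multiple database-search records: keeping highest score")
    db <- db[order(db$feature_id, -db$score), ]
    db <- db[!duplicated(db$feature_id), ]
  }
  dn <- filterDeNovo(deNovoIdents, alcMin = alcMin, minLength = minLength)
  if (nrow(dn)) {
    dn <- dn[order(dn$feature_id, -dn$alc, -nchar(dn$sequence),
                   dn$sequence), ]
    dn <- dn[!duplicated(dn$feature_id), ]
  }
  out <- data.frame(feature_id = featureIds,
                    sequence = NA_character_,
                    provenance = "unidentified",
                    score = NA_real_, alc = NA_real_,
                    low_confidence = FALSE, stringsAsFactors = FALSE)
  idb <- match(out$feature_id, db$feature_id)
  idn <- match(out$feature_id, dn$feature_id)
  for (k in seq_along(featureIds)) {
    b <- idb[k]; n <- idn[k]
    if (!is.na(b) && db$score[b] >= mascotMin) {
      out$sequence[k] <- db$sequence[b]
      out$provenance[k] <- "database_search"
      out$score[k] <- db$score[b]
    } else if (!is.na(n)) {
      out$sequence[k] <- dn$sequence[n]
      out$provenance[k] <- "de_novo"
      out$alc[k] <- dn$alc[n]
    } else if (!is.na(b)) {
      out$sequence[k] <- db$sequence[b]
      out$provenance[k] <- "database_search"
      out$score[k] <- db$score[b]
      out$low_confidence[k] <- TRUE
    }
  }
  out
}
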