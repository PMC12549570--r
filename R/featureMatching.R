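#' Match LC-MS features across two experiments
#'
#' Pairs unidentified features between experiments by physicochemical
#' coordinates: same charge, m/z difference strictly inside `mzTol`,
#' retention-time difference strictly inside `rtTol`, and (by default)
#' MS/MS scans present in both.  Candidate pairs are assigned one-to-one
#' greedily: the globally smallest `|delta m/z|` wins, ties broken by
#' smaller `|delta RT|`, then by feature id, so the result is
#' deterministic and symmetric in the two inputs.
#'
#' @param setA,setB Feature data.frames with columns `feature_id`, `mz`,
#'   `rt`, `charge`, `has_msms`.
#' @param mzTol m/z window (strict `<`, default 0.01 Th).
#' @param rtTol Retention-time window (strict `<`, default 1 min).
#' @param requireMsms `"both"` (default) or `"either"`.
#' @return data.frame of matches: `feature_id_a`, `feature_id_b`,
#'   `delta_mz`, `delta_rt`, `charge`.
#' @export
matchFeatures <- function(setA, setB, mzTol = 0.01, rtTol = 1.0,
                          requireMsms = c("both", "either")) {
  requireMsms <- match.arg(requireMsms)
  need <- c("feature_id", "mz", "rt", "charge", "has_msms")
  stopifnot(all(need %in% names(setA)), all(need %in% names(setB)))
  cand <- list()
  for (i in seq_len(nrow(setA))) {
    dz <- setB$charge == setA$charge[i]
    dmz <- abs(setB$mz - setA$mz[i])
    drt <- abs(setB$rt - setA$rt[i])
    ms <- if (requireMsms == "both") setA$has_msms[i] & setB$has_msms
          else setA$has_msms[i] | setB$has_msms
    hit <- which(dz & dmz < mzTol & drt < rtTol & ms)
    if (length(hit))
      cand[[length(cand) + 1L]] <- data.frame(
        i = i, j = hit, dmz = dmz[hit], drt = drt[hit],
        stringsAsFactors = FALSE)
  }
  empty <- data.frame(feature_id_a = character(),
                      feature_id_b = character(),
                      delta_mz = numeric(), delta_rt = numeric(),
                      charge = integer(), stringsAsFactors = FALSE)
  if (!length(cand)) return(empty)
  cand <- do.call(rbind, cand)
  cand <- cand[order(cand$dmz, cand$drt,
                     setA$feature_id[cand$i], setB$feature_id[cand$j]), ]
  usedA <- logical(nrow(setA)); usedB <- logical(nrow(setB))
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    if (!usedA[cand$i[k]] && !usedB[cand$j[k]]) {
      keep[k] <- TRUE
      usedA[cand$i[k]] <- TRUE
      usedB[cand$j[k]] <- TRUE
    }
  }
  cand <- cand[keep, , drop = FALSE]
  if (!nrow(cand)) return(empty)
  out <- data.frame(
    feature_id_a = setA$feature_id[cand$i],
    feature_id_b = setB$feature_id[cand$j],
    delta_mz = setB$mz[cand$j] - setA$mz[cand$i],
    delta_rt = setB$rt[cand$j] - setA$rt[cand$i],
    charge = setA$charge[cand$i], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
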