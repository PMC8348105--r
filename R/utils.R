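# shared internal helpers: metadata validation, group resolution, hashing

COHORTS <- c("control", "CCI", "RAP")
TIMEPOINTS <- c("none", "day1", "day14")
DISPOSITIONS <- c("good", "poor")

#' Validate a sample-metadata table
#'
#' Metadata must have columns `sample_id`, `cohort` (control/CCI/RAP),
#' `timepoint` (none/day1/day14) and `disposition` (good/poor/NA). Controls
#' carry timepoint `none` and no disposition.
#'
#' @param metadata A data.frame.
#' @return The metadata, invisibly, after validation.
#' @export
validate_metadata <- function(metadata) {
  need <- c("sample_id", "cohort", "timepoint", "disposition")
  miss <- setdiff(need, names(metadata))
  if (length(miss)) stop("metadata missing column(s): ", paste(miss, collapse = ", "))
  dup <- unique(metadata$sample_id[duplicated(metadata$sample_id)])
  if (length(dup)) stop("duplicate sample id(s) in metadata: ", paste(dup, collapse = ", "))
  bad <- setdiff(unique(metadata$cohort), COHORTS)
  if (length(bad)) stop("unknown cohort value(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(metadata$timepoint), TIMEPOINTS)
  if (length(bad)) stop("unknown timepoint value(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(metadata$disposition[!is.na(metadata$disposition)]), DISPOSITIONS)
  if (length(bad)) stop("unknown disposition value(s): ", paste(bad, collapse = ", "))
  ctrl <- metadata$cohort == "control"
  if (any(metadata$timepoint[ctrl] != "none")) {
    stop("control samples must have timepoint 'none'")
  }
  if (any(!is.na(metadata$disposition[ctrl]))) {
    stop("control samples must have no disposition")
  }
  invisible(metadata)
}

#' Canonical cohort-timepoint group label per sample
#'
#' Controls are labelled `"control"`; patient samples `"<cohort>_<timepoint>"`
#' (e.g. `"CCI_day1"`).
#'
#' @param metadata Validated sample metadata.
#' @return Named character vector, names = sample ids.
#' @export
sample_group <- function(metadata) {
  validate_metadata(metadata)
  g <- ifelse(metadata$cohort == "control", "control",
    paste(metadata$cohort, metadata$timepoint, sep = "_")
  )
  stats::setNames(g, metadata$sample_id)
}

#' Resolve a group specifier to sample ids
#'
#' A specifier is either a character vector of sample ids (all must exist) or
#' a single label of underscore-joined tokens drawn from cohort values
#' (`control`, `CCI`, `RAP`), timepoints (`day1`, `day14`, `none`) and
#' dispositions (`good`, `poor`); a sample must match every token. Examples:
#' `"control"`, `"CCI_day1"`, `"day14_poor"`, `"CCI_day14_good"`.
#'
#' @param metadata Validated sample metadata.
#' @param spec Group specifier.
#' @return Character vector of sample ids (metadata order).
#' @export
resolve_group <- function(metadata, spec) {
  validate_metadata(metadata)
  if (!is.character(spec) || length(spec) < 1) {
    stop("group specifier must be a character label or sample-id vector")
  }
  if (all(spec %in% metadata$sample_id)) {
    return(spec)
  }
  if (length(spec) != 1) {
    miss <- setdiff(spec, metadata$sample_id)
    stop("unknown sample id(s): ", paste(miss, collapse = ", "))
  }
  toks <- strsplit(spec, "_", fixed = TRUE)[[1]]
  keep <- rep(TRUE, nrow(metadata))
  for (tk in toks) {
    if (tk %in% COHORTS) {
      keep <- keep & metadata$cohort == tk
    } else if (tk %in% TIMEPOINTS) {
      keep <- keep & metadata$timepoint == tk
    } else if (tk %in% DISPOSITIONS) {
      keep <- keep & !is.na(metadata$disposition) & metadata$disposition == tk
    } else {
      stop("unknown group token '", tk, "' in specifier '", spec, "'")
    }
  }
  ids <- metadata$sample_id[keep]
  if (length(ids) == 0) stop("group '", spec, "' matches no samples")
  ids
}

# FNV-1a 32-bit hash of a character scalar; used to stamp run provenance.
# Arithmetic is done on 16-bit halves so every intermediate fits in a double.
fnv1a32 <- function(x) {
  bytes <- utf8ToInt(enc2utf8(paste(x, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    lo <- bitwXor(h %% 65536, b)
    hi <- h %/% 65536
    h <- (lo * 16777619 + (hi * 16777619 %% 65536) * 65536) %% 4294967296
  }
  paste0(sprintf("%04x", h %/% 65536), sprintf("%04x", h %% 65536))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# unbiased per-row variance of a numeric matrix (n - 1 denominator)
row_vars <- function(v) {
  n <- ncol(v)
  mu <- rowMeans(v)
  rowSums((v - mu)^2) / (n - 1)
}
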