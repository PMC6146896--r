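#' Rank-ordered calibration/prediction split
#'
#' Sorts the samples from lowest to highest reference concentration (stable:
#' ties keep original order) and assigns, in each consecutive block of four,
#' the first three to the calibration set and the fourth to the prediction
#' set. A trailing partial block goes to calibration, so the prediction set is
#' a strict every-fourth subsample of the concentration-ordered samples. With
#' 68 samples this yields 51 calibration and 17 prediction samples.
#'
#' @param reference numeric vector of reference concentrations, length >= 4.
#' @return An object of class `libs_split`: list with integer index vectors
#'   `calibration` and `prediction` (indices into the original sample order).
#' @examples
#' split_rank_ordered(runif(68))
#' @export
split_rank_ordered <- function(reference) {
  n <- length(reference)
  if (n < 4) stop("at least 4 samples are required for a 3-of-4 split")
  ord <- order(reference)                 # stable; ties by original index
  pos <- seq_len(n)
  pred <- ord[pos %% 4L == 0L]
  cal <- ord[pos %% 4L != 0L]
  structure(list(calibration = sort(cal), prediction = sort(pred)),
            class = "libs_split")
}

#' @export
print.libs_split <- function(x, ...) {
  cat("<libs_split> ", length(x$calibration), " calibration / ",
      length(x$prediction), " prediction samples\n", sep = "")
  invisible(x)
}

#' Write a split assignment as a two-column id/assignment text file
#'
#' @param split a [split_rank_ordered()] result.
#' @param ids sample identifiers, one per original sample.
#' @param path file path.
#' @export
write_split <- function(split, ids, path) {
  stopifnot(inherits(split, "libs_split"))
  assignment <- rep("calibration", length(ids))
  assignment[split$prediction] <- "prediction"
  data.table::fwrite(data.table::data.table(id = ids, set = assignment),
                     path, sep = "\t")
  invisible(path)
}
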