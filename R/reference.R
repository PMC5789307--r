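#' Published reference confusion matrices
#'
#' The leave-one-out QDA confusion matrices reported by the original ear /
#' collar / leg sheep-lameness field study, shipped as plain-text fixtures.
#' They let the performance arithmetic ([prediction_accuracy()],
#' [performance()]) be checked against the study's printed percentages, and
#' serve as worked-example inputs. Analysis I includes lame grazing among
#' the candidate classes; Analysis II excludes it. Counts are kept exactly
#' as printed (including two column totals that differ by one event from
#' the study's epoch inventory).
#'
#' @param deployment `"ear"`, `"collar"` or `"leg"`.
#' @param analysis `"I"` or `"II"`.
#' @return A [confusion_matrix()] (rows predicted, columns observed).
#' @examples
#' cm <- ref_confusion("ear", "II")
#' round(100 * prediction_accuracy(cm, "lame_walking"))
#' @export
ref_confusion <- function(deployment = c("ear", "collar", "leg"),
                          analysis = c("II", "I")) {
  deployment <- match.arg(deployment)
  analysis <- match.arg(analysis)
  path <- system.file(
    "extdata",
    sprintf("ref_cm_analysis%s_%s.csv",
            if (analysis == "I") "1" else "2", deployment),
    package = "ovisense", mustWork = TRUE)
  df <- read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df$predicted
  confusion_matrix(m)
}
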