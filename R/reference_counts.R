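#' Published reference cross-tabulations for the 484-subject cohort
#'
#' Type-by-cluster subject counts reported for a 484-subject tibial
#' rotation cohort: for each of the four rotations, the real counts under
#' the anthropometric rule and the counts recovered by the hybrid PSO-KM
#' and plain KM clusterings. These are the canonical inputs for the
#' evaluation arithmetic ([report_from_counts()]) and let the published
#' comparison tables be recomputed exactly.
#'
#' @param rotation Optional rotation to subset to (`"rter"`, `"rtir"`,
#'   `"lter"`, `"ltir"`).
#' @return A nested list: `counts[[rotation]][[source]]` is a 3 x 3
#'   integer matrix (types in rows, clusters in columns), with `source`
#'   one of `"real"`, `"psokm"`, `"km"`.
#' @examples
#' cc <- rotation_reference_counts("ltir")
#' colSums(cc$real)   # 52 249 183
#' colSums(cc$psokm)  # 46 239 199
#' @export
rotation_reference_counts <- function(rotation = NULL) {
  path <- system.file("extdata", "rotation_reference_counts.csv",
                      package = "psokm", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- lapply(split(df, df$rotation), function(rot) {
    lapply(split(rot, rot$source), function(src) {
      src <- src[order(match(src$type, c("TYPE1", "TYPE2", "TYPE3"))), ]
      m <- as.matrix(src[, c("c1", "c2", "c3")])
      storage.mode(m) <- "integer"
      dimnames(m) <- list(type = c("TYPE1", "TYPE2", "TYPE3"),
                          cluster = c("C1", "C2", "C3"))
      m
    })
  })
  out <- out[c("rter", "rtir", "lter", "ltir")]
  if (!is.null(rotation)) {
    rotation <- match.arg(rotation, names(out))
    return(out[[rotation]])
  }
  out
}
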