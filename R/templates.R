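# Canonical 19-channel reference maps for classes A-D.

#' Canonical 19-channel reference templates
#'
#' Idealised approximations of the four canonical microstate topographies on
#' the 19-electrode 10-20 montage, built synthetically from electrode
#' geometry (A: left-posterior to right-frontal gradient; B: mirrored
#' right-posterior to left-frontal gradient; C: anterior-posterior axis;
#' D: fronto-central versus peripheral focus). They fix the A-D labelling
#' order during alignment and are user-replaceable via the `reference`
#' argument of [microstate_fit()] / [align_to_reference()]; they are not
#' empirical grand-average maps.
#'
#' @param path optional path to a JSON file with fields `channels` and
#'   `templates` (list of named rows); defaults to the packaged file.
#' @return 4 x 19 matrix, rows named A-D, columns named by electrode;
#'   zero-mean unit-norm rows.
#' @export
canonical_templates <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "canonical_templates_19ch_synthetic.json",
                        package = "microfuse")
  }
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- do.call(rbind, obj$templates)
  colnames(m) <- obj$channels
  t(apply(m, 1L, normalize_map))
}
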