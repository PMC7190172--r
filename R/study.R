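#' Run the manual-versus-automated study on a synthetic cohort
#'
#' Convenience driver reproducing the full comparison design on generated
#' data: every subject is co-registered automatically (from
#' template-jittered fiducial estimates), the simulated manual transform is
#' evaluated against the same surface, and optionally the automated run is
#' repeated against a de-faced copy of each surface.
#'
#' @param cohort a `cohort_dataset` from [generate_cohort()].
#' @param config a [coreg_config()].
#' @param defaced also run automated co-registration on de-faced surfaces.
#' @return a list with `auto`, `manual` (lists of `coreg_result`),
#'   `defaced` (present when requested), `headshape_counts`, and
#'   `ground_truth` (list of `rigid_transform`).
#' @export
run_cohort_study <- function(cohort, config = coreg_config(),
                             defaced = FALSE) {
  stopifnot(inherits(cohort, "cohort_dataset"))
  auto <- list()
  manual <- list()
  defd <- list()
  for (i in seq_along(cohort$subjects)) {
    s <- cohort$subjects[[i]]
    auto[[i]] <- auto_coregister(s$headshape, s$surface,
                                 s$fiducial_estimates, config)
    manual[[i]] <- evaluate_transform(s$headshape, s$surface, s$manual,
                                      config)
    if (isTRUE(defaced)) {
      defd[[i]] <- auto_coregister(s$headshape, deface(s$surface),
                                   s$fiducial_estimates, config)
    }
  }
  out <- list(auto = auto, manual = manual,
              headshape_counts = vapply(cohort$subjects,
                                        function(s) s$headshape$n, 0),
              ground_truth = lapply(cohort$subjects, `[[`, "ground_truth"))
  if (isTRUE(defaced)) out$defaced <- defd
  out
}
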