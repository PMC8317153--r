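# Frozen configuration: pharmacophore alphabet + rules, descriptor manifest,
# SMARTS fragment panel. All three ship as versioned JSON under extdata; the
# feature layout of every signature vector is derived from them.

.molsig_env <- new.env(parent = emptyenv())

.read_config <- function(fname) {
  path <- system.file("extdata", fname, package = "molsig", mustWork = TRUE)
  jsonlite::read_json(path, simplifyVector = TRUE)
}

.pharm_config <- function() {
  if (is.null(.molsig_env$pharm)) .molsig_env$pharm <- .read_config("pharmacophore_rules.json")
  .molsig_env$pharm
}

.descriptor_config <- function() {
  if (is.null(.molsig_env$desc)) .molsig_env$desc <- .read_config("descriptor_manifest.json")
  .molsig_env$desc
}

.panel_config <- function() {
  if (is.null(.molsig_env$panel)) .molsig_env$panel <- .read_config("fragment_panel.json")
  .molsig_env$panel
}

#' Pharmacophore class alphabet
#'
#' The fixed, ordered 8-class alphabet used to label atoms. The ordering is
#' frozen by the shipped configuration and determines the layout of the
#' signature block of every feature vector.
#'
#' @return Character vector of length 8.
#' @export
#' @examples
#' pharmacophore_classes()
pharmacophore_classes <- function() {
  as.character(.pharm_config()$alphabet)
}

#' Descriptor manifest
#'
#' Ordered manifest of the 48 general physicochemical descriptors that form
#' the tail of every feature vector.
#'
#' @return A tibble with columns `name`, `unit`, `description`.
#' @export
descriptor_manifest <- function() {
  as_tibble(.descriptor_config()$descriptors)
}

#' Signature feature names
#'
#' The frozen, ordered names of the full feature vector: 216 signature
#' entries (`Sig:<ClassA>:<ClassB>:d<k>` for the 36 unordered class pairs and
#' distance cutoffs k = 1..6) followed by the 48 descriptor names. Length is
#' always 264.
#'
#' @param cutoffs Integer vector of distance cutoffs (frozen default `1:6`).
#' @return Character vector of length 264.
#' @export
#' @examples
#' length(feature_names())
feature_names <- function(cutoffs = 1:6) {
  cls <- pharmacophore_classes()
  sig <- character(0)
  for (a in seq_along(cls)) {
    for (b in a:length(cls)) {
      sig <- c(sig, sprintf("Sig:%s:%s:d%d", cls[a], cls[b], cutoffs))
    }
  }
  c(sig, descriptor_manifest()$name)
}

#' Configuration hash
#'
#' Stable hash of the shipped configuration (pharmacophore rules, descriptor
#' manifest, fragment panel). Logged alongside every run so outputs can be
#' traced to the exact feature layout that produced them.
#'
#' @return A character scalar.
#' @export
config_hash <- function() {
  rlang::hash(list(.pharm_config(), .descriptor_config(), .panel_config()))
}

#' SMARTS fragment panel
#'
#' The fixed panel of substructure patterns used by [fragment_frequencies()].
#'
#' @return A tibble with columns `name`, `smarts`, `provenance`.
#' @export
fragment_panel <- function() {
  as_tibble(.panel_config()$patterns)
}
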