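#' Person-knowledge task battery
#'
#' The ten experimental tasks probe five domains of person-knowledge (nominal,
#' physical, social, episodic, biographical), two tasks per domain. The five
#' domains group into three macro-domains of cortical signature: `memories`
#' (episodic + biographical), `traits` (social + physical) and `nominal`.
#'
#' @return A data frame with columns `task`, `domain` and `macro_domain`
#'   (ten rows, one per task).
#' @examples
#' person_knowledge_tasks()
#' @export
person_knowledge_tasks <- function() {
  df <- data.frame(
    task = c("common_name", "common_surname",
             "attractive", "distinctive",
             "friendly", "trustworthy",
             "familiar", "first_memory",
             "how_many_facts", "occupation"),
    domain = rep(c("nominal", "physical", "social", "episodic", "biographical"),
                 each = 2),
    stringsAsFactors = FALSE
  )
  macro <- c(nominal = "nominal", physical = "traits", social = "traits",
             episodic = "memories", biographical = "memories")
  df$macro_domain <- unname(macro[df$domain])
  df
}

#' 1-back control conditions
#'
#' Two 1-back matching control tasks: famous-name matching and monument-name
#' matching. Baseline subtraction uses the famous-name condition so that the
#' contribution of reading a person's name per se is removed.
#'
#' @return Character vector of length 2; the first element is the condition
#'   used as baseline.
#' @export
control_conditions <- function() {
  c("name_1back", "monument_1back")
}

#' ROI sphere specifications (21 person-selective peaks)
#'
#' Peak MNI coordinates of the 21 face/person-selective regions used as sphere
#' centres (7.5 mm radius), together with reported post-conjunction sizes in
#' voxels, loaded verbatim from the packaged table.
#'
#' Two oddities of the printed table are preserved verbatim and flagged with
#' warnings rather than silently corrected: right FFA and right IFG share
#' identical coordinates, and the OFC and ATFP rows carry x-signs inconsistent
#' with their hemisphere labels.
#'
#' @param validate Logical; emit validation warnings for the known table
#'   oddities (default `TRUE`).
#' @return Data frame with columns `region`, `hemisphere`, `x`, `y`, `z`,
#'   `size_voxels` and a derived unique `name` (`region_hemisphereInitial`).
#' @examples
#' specs <- suppressWarnings(roi_sphere_specs())
#' nrow(specs)  # 21
#' @export
roi_sphere_specs <- function(validate = TRUE) {
  path <- system.file("extdata", "roi_spheres.csv", package = "netrsa",
                      mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$name <- paste(df$region, substr(df$hemisphere, 1L, 1L), sep = "_")
  stopifnot(!anyDuplicated(df$name))
  if (validate) {
    coords <- paste(df$x, df$y, df$z)
    dup <- duplicated(coords) | duplicated(coords, fromLast = TRUE)
    if (any(dup)) {
      warning("duplicate peak coordinates in ROI table: ",
              paste(df$name[dup], collapse = ", "),
              " (loaded verbatim)", call. = FALSE)
    }
    sign_odd <- (df$hemisphere == "Left" & df$x > 0) |
      (df$hemisphere == "Right" & df$x < 0)
    if (any(sign_odd)) {
      warning("hemisphere label and x-coordinate sign disagree for: ",
              paste(df$name[sign_odd], collapse = ", "),
              " (loaded verbatim)", call. = FALSE)
    }
  }
  df
}

#' Core and extended region sets
#'
#' The core system comprises the perceptual face regions (OFA, FFA, pSTS); the
#' extended system is the remaining 15 person-selective ROIs associated with
#' non-perceptual person cognition.
#'
#' @param set `"core"` or `"extended"`.
#' @return Character vector of ROI names (`region_hemisphere` form).
#' @export
region_set <- function(set = c("extended", "core")) {
  set <- match.arg(set)
  specs <- roi_sphere_specs(validate = FALSE)
  core_regions <- c("OFA", "FFA", "pSTS")
  if (set == "core") specs$name[specs$region %in% core_regions]
  else specs$name[!specs$region %in% core_regions]
}

#' Tripartite regional model membership (I/E/C)
#'
#' The theoretical model of extended-system organisation partitions regions
#' into internalised-cognition regions, control regions and ventromedial
#' (externalised) regions. Membership is read from a packaged JSON
#' configuration file rather than hard-coded, so alternative groupings can be
#' supplied.
#'
#' @param path Optional path to a JSON file mapping group names to region
#'   names; defaults to the packaged I/E/C definition.
#' @return Named character vector: ROI name (per hemisphere) -> group.
#' @export
iec_partition <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "iec_partition.json", package = "netrsa",
                        mustWork = TRUE)
  }
  groups <- jsonlite::read_json(path, simplifyVector = TRUE)
  specs <- roi_sphere_specs(validate = FALSE)
  out <- character(0)
  for (g in names(groups)) {
    nm <- specs$name[specs$region %in% groups[[g]]]
    out[nm] <- g
  }
  out
}

#' Default ROI-group partition used by the synthetic generator
#'
#' Assigns every one of the 21 ROIs to one of three coordination groups,
#' mirroring the tripartite subsystem structure reported for face-cued
#' person-knowledge access: an internalised/default-mode group (precuneus,
#' vmPFC, dmPFC, ATL, AG), a perceptual-prefrontal control group (core face
#' regions plus IFG and OFC) and an anterior-ventral group (ATFP, amygdala).
#'
#' @return Named character vector: ROI name -> group in
#'   `{"internalised", "control", "ventromedial"}`.
#' @export
default_roi_partition <- function() {
  specs <- roi_sphere_specs(validate = FALSE)
  grp <- c(Precuneus = "internalised", vmPFC = "internalised",
           dmPFC = "internalised", ATL = "internalised", AG = "internalised",
           OFA = "control", FFA = "control", pSTS = "control",
           IFG = "control", OFC = "control",
           ATFP = "ventromedial", Amygdala = "ventromedial")
  out <- unname(grp[specs$region])
  names(out) <- specs$name
  out
}
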