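#' Atlas and hemisphere handling
#'
#' The analyses operate on a fixed anatomical parcellation of the brain into
#' `R` regions (default 246, the region count of the Brainnetome-style
#' parcellation used throughout). Region ids are 1-based and contiguous; the
#' default hemisphere coding assigns odd ids to the left and even ids to the
#' right hemisphere, so both hemispheres hold exactly `R/2` regions. A
#' non-default atlas may override the coding via its `hemisphere` column.
#'
#' @name atlas
NULL

#' Default DMN region ids for the 246-region atlas
#'
#' A documented default set of subregion ids covering the canonical
#' Default-Mode Network hubs: middle temporal gyrus (81--88), inferior
#' parietal lobule (135--146) and the cingulate subregions containing the
#' anterior and posterior cingulate cortex (175--188). The set is
#' configurable through the atlas table's `dmn_member` column; this default
#' is only meaningful for the 246-region parcellation.
#'
#' @return Integer vector of region ids (17 per hemisphere).
#' @export
default_dmn_ids <- function() {
  as.integer(c(81:88, 135:146, 175:188))
}

#' Construct the default atlas table
#'
#' @param n_regions Number of regions `R` (even, >= 4). Default 246.
#' @param dmn_ids Integer region ids flagged as DMN members. Defaults to
#'   [default_dmn_ids()] when `n_regions == 246`, otherwise empty.
#' @return A `data.frame` with columns `region_id`, `region_name`,
#'   `hemisphere` and `dmn_member`. Region names are synthetic placeholders
#'   (`ROI_###_L/R`); the real study parcellation is not redistributed here.
#' @export
default_atlas <- function(n_regions = 246L,
                          dmn_ids = if (n_regions == 246L) default_dmn_ids() else integer()) {
  n_regions <- as.integer(n_regions)
  if (n_regions < 4L || n_regions %% 2L != 0L) {
    stop("n_regions must be an even integer >= 4, got ", n_regions)
  }
  id <- seq_len(n_regions)
  hemi <- ifelse(id %% 2L == 1L, "left", "right")
  atlas <- data.frame(
    region_id = id,
    region_name = sprintf("ROI_%03d_%s", id, ifelse(hemi == "left", "L", "R")),
    hemisphere = hemi,
    dmn_member = id %in% as.integer(dmn_ids),
    stringsAsFactors = FALSE
  )
  validate_atlas(atlas, contiguous = TRUE)
}

#' Validate an atlas table
#'
#' Checks id uniqueness and hemisphere labels. A full atlas (as built by
#' [default_atlas()] or read from file) must have ids contiguous from 1 to
#' `R`; a restricted sub-atlas (see [dmn_subatlas()]) keeps its original,
#' possibly non-contiguous ids.
#'
#' @param atlas Atlas `data.frame` (see [default_atlas()]).
#' @param contiguous Require ids to be exactly `1..nrow(atlas)`.
#' @return The validated atlas, rows ordered by `region_id`.
#' @export
validate_atlas <- function(atlas, contiguous = FALSE) {
  req <- c("region_id", "region_name", "hemisphere", "dmn_member")
  if (!all(req %in% names(atlas))) {
    stop("atlas must have columns: ", paste(req, collapse = ", "))
  }
  r <- nrow(atlas)
  atlas$region_id <- as.integer(atlas$region_id)
  if (anyDuplicated(atlas$region_id) || any(atlas$region_id < 1L)) {
    stop("atlas region_ids must be unique positive integers")
  }
  if (contiguous && !identical(sort(atlas$region_id), seq_len(r))) {
    stop("atlas region_ids must be contiguous from 1 to ", r)
  }
  if (!all(atlas$hemisphere %in% c("left", "right"))) {
    stop("atlas hemisphere must be 'left' or 'right'")
  }
  atlas <- atlas[order(atlas$region_id), , drop = FALSE]
  rownames(atlas) <- NULL
  atlas$dmn_member <- as.logical(atlas$dmn_member)
  atlas
}

#' Read an atlas definition from CSV
#'
#' Expected header: `region_id,region_name,hemisphere,dmn_member` with
#' `hemisphere` in `{left,right}` and `dmn_member` in `{0,1}`.
#'
#' @param path Path to the CSV file.
#' @return Validated atlas `data.frame`.
#' @export
read_atlas <- function(path) {
  if (!file.exists(path)) stop("atlas file not found: ", path)
  atlas <- utils::read.csv(path, stringsAsFactors = FALSE)
  atlas$dmn_member <- as.logical(as.integer(atlas$dmn_member))
  validate_atlas(atlas, contiguous = TRUE)
}

#' Hemisphere of a region
#'
#' Under the default odd/even coding, odd region ids are left-hemispheric
#' and even ids right-hemispheric; a supplied atlas table overrides this.
#'
#' @param region_id Integer region id(s) in `1..R`.
#' @param atlas Optional atlas table; when `NULL` the default coding is used
#'   with `n_regions` as the upper bound.
#' @param n_regions Region count used for range checking when `atlas` is `NULL`.
#' @return Character vector, `"left"` or `"right"`.
#' @export
hemisphere_of <- function(region_id, atlas = NULL, n_regions = 246L) {
  region_id <- as.integer(region_id)
  if (is.null(atlas)) {
    r <- as.integer(n_regions)
    bad <- which(is.na(region_id) | region_id < 1L | region_id > r)
    if (length(bad) > 0L) {
      stop("region_id out of range 1..", r, ": ", paste(region_id[bad], collapse = ", "))
    }
    ifelse(region_id %% 2L == 1L, "left", "right")
  } else {
    idx <- match(region_id, atlas$region_id)
    if (anyNA(idx)) {
      stop("region_id not in atlas: ", paste(region_id[is.na(idx)], collapse = ", "))
    }
    atlas$hemisphere[idx]
  }
}

#' Classify an edge into a hemispheric compartment
#'
#' Every unordered off-diagonal region pair belongs to exactly one of three
#' compartments: `intra_left`, `intra_right`, or `interhemispheric`.
#' Self-edges are excluded from all analyses and raise an error.
#'
#' @param i,j Region ids (vectorized, `i != j` elementwise).
#' @inheritParams hemisphere_of
#' @return Character vector of compartment labels.
#' @export
classify_edge <- function(i, j, atlas = NULL, n_regions = 246L) {
  if (any(i == j)) stop("self-edges (i == j) are excluded from all analyses")
  hi <- hemisphere_of(i, atlas, n_regions)
  hj <- hemisphere_of(j, atlas, n_regions)
  ifelse(hi != hj, "interhemispheric",
         ifelse(hi == "left", "intra_left", "intra_right"))
}

#' Compartment label matrix for an atlas
#'
#' @param atlas Atlas table.
#' @return `R x R` character matrix with `NA` on the diagonal and compartment
#'   labels (`intra_left`/`intra_right`/`interhemispheric`) off it.
#' @export
edge_compartments <- function(atlas) {
  atlas <- validate_atlas(atlas)
  h <- atlas$hemisphere
  left <- h == "left"
  comp <- matrix("interhemispheric", nrow(atlas), nrow(atlas))
  comp[outer(left, left, "&")] <- "intra_left"
  comp[outer(!left, !left, "&")] <- "intra_right"
  diag(comp) <- NA_character_
  comp
}

#' Restrict an atlas to its DMN members
#'
#' Returns the atlas rows flagged as DMN members, hemisphere labels
#' preserved. Downstream operations accept the restricted atlas unchanged
#' (matrices are subset to the same ids in atlas order).
#'
#' @param atlas Atlas table with `dmn_member` flags set.
#' @return The restricted atlas `data.frame` (row order by region_id).
#' @export
dmn_subatlas <- function(atlas) {
  atlas <- validate_atlas(atlas)
  sub <- atlas[atlas$dmn_member, , drop = FALSE]
  if (nrow(sub) == 0L) stop("DMN member set is empty; set dmn_member flags in the atlas")
  for (h in c("left", "right")) {
    if (sum(sub$hemisphere == h) < 2L) {
      stop("DMN analysis requires >= 2 DMN regions in each hemisphere (", h, " has ",
           sum(sub$hemisphere == h), ")")
    }
  }
  rownames(sub) <- NULL
  sub
}
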