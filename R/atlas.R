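# Ten-region anatomical atlas of the 48-hpf embryo, in the injection-site
# coordinate frame: origin at the pericardial space (PCS), +x toward the tail
# (anteroposterior), +y toward dorsal. Units are micrometres.

.atlas_regions <- c("PCS", "Yolk", "CHT", "CF", "ISV",
                    "PHBC", "PCV", "PMBC", "DLAV", "AA1")

#' Default anatomical region atlas
#'
#' Axis-aligned rectangular extents for the ten migration regions used to
#' score xenografted-cell tropism: pericardial space (PCS, contains the
#' injection site at the origin), yolk, caudal hematopoietic tissue (CHT),
#' caudal fin (CF), intersegmental vessels (ISV), primordial hindbrain channel
#' (PHBC), posterior cardinal vein (PCV), primordial midbrain channel (PMBC),
#' dorsal longitudinal anastomotic vessel (DLAV), and mandibular arch (AA1).
#'
#' The geometry is a schematic tiling of the embryo bounding box
#' (x in [-600, 3000], y in [-500, 500] micrometres): the anterior band holds
#' PCS/AA1/PMBC/PHBC, the medial band Yolk/ISV/DLAV, the posterior band
#' CHT/PCV, and the caudal fin closes the tail. It is a configuration, not an
#' anatomical ground truth: pass an edited atlas (see \code{\link{read_atlas}})
#' to use measured extents.
#'
#' @return data frame with columns \code{region, x0, x1, y0, y1}.
#' @examples
#' region_atlas()
#' @export
region_atlas <- function() {
  a <- data.frame(
    region = .atlas_regions,
    x0 = c(-600,  400, 1600, 2600,  400, -600, 1600, -600,  400, -600),
    x1 = c( 400, 1600, 2600, 3000, 1600,  400, 2600,  400, 1600,  400),
    y0 = c(-500, -500, -500, -500, -100,  375, -100,  250,  250,  100),
    y1 = c( 100, -100, -100,  500,  250,  500,  500,  375,  500,  250),
    stringsAsFactors = FALSE
  )
  validate_atlas(a)
}

#' @rdname region_atlas
#' @param atlas candidate atlas data frame.
#' @export
validate_atlas <- function(atlas) {
  need <- c("region", "x0", "x1", "y0", "y1")
  if (!all(need %in% names(atlas))) {
    stop("atlas must have columns: ", paste(need, collapse = ", "))
  }
  if (nrow(atlas) != 10L || !setequal(atlas$region, .atlas_regions)) {
    stop("atlas must define exactly the 10 regions: ",
         paste(.atlas_regions, collapse = ", "))
  }
  if (anyDuplicated(atlas$region)) stop("duplicated region names in atlas")
  if (any(atlas$x1 <= atlas$x0) || any(atlas$y1 <= atlas$y0)) {
    stop("degenerate rectangle in atlas (x1 <= x0 or y1 <= y0)")
  }
  atlas[match(.atlas_regions, atlas$region), , drop = FALSE]
}

#' Read or write a region atlas
#'
#' Atlases are stored as YAML or JSON mapping each region name to its
#' rectangle \code{[x0, x1, y0, y1]} in micrometres.
#'
#' @param path file path; format chosen by extension (.yaml/.yml or .json).
#' @return \code{read_atlas} returns a validated atlas data frame.
#' @export
read_atlas <- function(path) {
  if (!file.exists(path)) stop("atlas file not found: ", path)
  lst <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  a <- do.call(rbind, lapply(names(lst), function(r) {
    v <- as.numeric(lst[[r]])
    data.frame(region = r, x0 = v[1], x1 = v[2], y0 = v[3], y1 = v[4],
               stringsAsFactors = FALSE)
  }))
  validate_atlas(a)
}

#' @rdname read_atlas
#' @param atlas atlas data frame to write.
#' @export
write_atlas <- function(atlas, path) {
  atlas <- validate_atlas(atlas)
  lst <- setNames(
    lapply(seq_len(nrow(atlas)),
           function(i) as.numeric(atlas[i, c("x0", "x1", "y0", "y1")])),
    atlas$region
  )
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(lst, path)
  } else {
    jsonlite::write_json(lst, path, digits = NA)
  }
  invisible(path)
}

#' Assign foci to atlas regions
#'
#' Each focus is labeled with the region whose rectangle contains it.
#' Containment uses half-open rectangles \code{[x0, x1) x [y0, y1)} so a focus
#' on a shared edge belongs to exactly one region; a focus outside every
#' rectangle is mapped to the nearest region by Euclidean distance to the
#' rectangle, making the assignment total.
#'
#' @param foci data frame with numeric columns \code{x_um} and \code{y_um}.
#' @param atlas region atlas (default \code{\link{region_atlas}()}).
#' @return \code{foci} with a \code{region} character column (replaced if
#'   already present).
#' @export
assign_regions <- function(foci, atlas = region_atlas()) {
  atlas <- validate_atlas(atlas)
  stopifnot(all(c("x_um", "y_um") %in% names(foci)))
  x <- foci$x_um
  y <- foci$y_um
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("non-finite focus coordinates")
  }
  n <- length(x)
  region <- character(n)
  # containment matrix: n x 10, first matching region wins (atlas order)
  for (i in seq_len(nrow(atlas))) {
    inside <- x >= atlas$x0[i] & x < atlas$x1[i] &
              y >= atlas$y0[i] & y < atlas$y1[i]
    region[inside & region == ""] <- atlas$region[i]
  }
  miss <- which(region == "")
  if (length(miss)) {
    for (j in miss) {
      dx <- pmax(atlas$x0 - x[j], 0, x[j] - atlas$x1)
      dy <- pmax(atlas$y0 - y[j], 0, y[j] - atlas$y1)
      region[j] <- atlas$region[which.min(dx^2 + dy^2)]
    }
  }
  foci$region <- region
  foci
}
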