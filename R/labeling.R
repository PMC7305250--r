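#' Extract vertebra instances from a semantic class mask
#'
#' Binarizes the foreground (any class > 0), labels 26-connected components,
#' discards components smaller than `min_voxels` (speckle), assigns each
#' surviving component the majority class of its voxels, and returns the
#' instances sorted by centroid z, superior to inferior. 26-connectivity is
#' used so oblique cortical voxel chains do not fragment an instance.
#'
#' @param mask a [class_mask].
#' @param min_voxels minimum component size in voxels (default 100, about
#'   0.4 cm^3 at 2 x 2 x 1 mm voxels).
#' @return list of `vertebra_instance` objects: `name` (NA until
#'   [assign_names()]), `class_id`, `voxels` (1-based linear indices),
#'   `n_voxels`, `centroid` `(z, y, x)` in voxels, `z_extent`
#'   `(z_min, z_max)` inclusive, `flags`.
#' @export
extract_components <- function(mask, min_voxels = 100) {
  stopifnot(inherits(mask, "class_mask"))
  d <- dim(mask$labels)
  lab <- cc_label_cpp(as.integer(mask$labels > 0), as.integer(d), TRUE)
  if (!any(lab > 0)) return(list())
  comps <- split(seq_along(lab), lab)
  comps[["0"]] <- NULL
  comps <- comps[lengths(comps) >= min_voxels]
  if (!length(comps)) return(list())
  inst <- lapply(comps, function(vox) {
    coords <- arrayInd(vox, d)
    classes <- tabulate(mask$labels[vox], nbins = 3)
    structure(list(name = NA_character_,
                   class_id = which.max(classes),
                   voxels = vox,
                   n_voxels = length(vox),
                   centroid = colMeans(coords),
                   z_extent = range(coords[, 1]),
                   flags = character()),
              class = "vertebra_instance")
  })
  inst <- unname(inst)
  inst[order(vapply(inst, function(i) i$centroid[1], 0))]
}

#' Assign anatomical names to sorted vertebra instances
#'
#' Lumbar (class 3) instances are named L1, L2 from the top down; thoracic
#' (class 1 and 2) instances are named from the bottom up, the most inferior
#' thoracic instance becoming T12, then T11 and so on. Extras beyond the
#' anatomical range -- a third class-3 instance, or a thirteenth thoracic
#' instance (a known failure mode when the network over-segments a class) --
#' are left unnamed and flagged. When no lumbar instance is present the
#' bottom-up thoracic rule still anchors the most inferior thoracic instance
#' as T12; the result is flagged low confidence because the true inferior
#' extent of the field of view is then unknown.
#'
#' @param instances list of `vertebra_instance`, sorted superior to inferior
#'   (as returned by [extract_components()]).
#' @return the same list with `name` and `flags` filled in; attribute
#'   `warnings` collects human-readable messages.
#' @export
assign_names <- function(instances) {
  if (!length(instances)) return(structure(list(), warnings = character()))
  stopifnot(!is.unsorted(vapply(instances, function(i) i$centroid[1], 0)))
  warnings <- character()
  is_lumbar <- vapply(instances, function(i) i$class_id == 3L, TRUE)
  lumbar_pos <- which(is_lumbar)
  thoracic_pos <- which(!is_lumbar)

  for (k in seq_along(lumbar_pos)) {           # top down: L1, L2, ...
    if (k <= 2) {
      instances[[lumbar_pos[k]]]$name <- paste0("L", k)
    } else {
      instances[[lumbar_pos[k]]]$flags <-
        c(instances[[lumbar_pos[k]]]$flags, "extra_lumbar")
      warnings <- c(warnings, sprintf("more than 2 lumbar instances: extra at z=%.1f left unnamed",
                                      instances[[lumbar_pos[k]]]$centroid[1]))
    }
  }
  nt <- length(thoracic_pos)
  for (k in seq_len(nt)) {                     # bottom up: T12, T11, ...
    pos <- thoracic_pos[nt - k + 1]
    if (k <= 12) {
      instances[[pos]]$name <- paste0("T", 13 - k)
    } else {
      instances[[pos]]$flags <- c(instances[[pos]]$flags, "extra_thoracic")
      warnings <- c(warnings, sprintf("%d thoracic instances: most superior left unnamed", nt))
    }
  }
  if (!length(lumbar_pos) && nt > 0) {
    anchor <- thoracic_pos[nt]
    instances[[anchor]]$flags <- c(instances[[anchor]]$flags, "no_lumbar_anchor")
    warnings <- c(warnings, "no lumbar instance: thoracic naming anchored at most inferior instance (low confidence)")
  }
  structure(instances, warnings = warnings)
}

#' Render named instances as an instance mask
#'
#' @param instances list of (named) `vertebra_instance`.
#' @param dim integer(3) volume dims `(z, y, x)`.
#' @param spacing voxel spacing `(z, y, x)` in mm.
#' @return an [instance_mask]; instance ids follow list order, background 0.
#' @export
to_instance_mask <- function(instances, dim, spacing = c(1, 1, 1)) {
  lab <- array(0L, dim = dim)
  all_vox <- unlist(lapply(instances, `[[`, "voxels"))
  if (length(all_vox) != length(unique(all_vox)))
    stop("to_instance_mask: instances overlap", call. = FALSE)
  nm <- character(length(instances))
  for (i in seq_along(instances)) {
    lab[instances[[i]]$voxels] <- i
    nm[i] <- instances[[i]]$name
  }
  mapping <- setNames(seq_along(instances), nm)
  instance_mask(lab, mapping, spacing)
}

#' Full labeling stage: class mask to named instances
#'
#' @param mask a [class_mask].
#' @param min_voxels see [extract_components()].
#' @return list with `instances` (named), `instance_mask`, `warnings`.
#' @export
label_vertebrae <- function(mask, min_voxels = 100) {
  instances <- assign_names(extract_components(mask, min_voxels))
  im <- if (length(instances))
    to_instance_mask(instances, dim(mask$labels), mask$spacing)
  else instance_mask(array(0L, dim(mask$labels)), integer(0), mask$spacing)
  list(instances = instances, instance_mask = im,
       warnings = attr(instances, "warnings"))
}

#' Write the instance sidecar table
#'
#' One row per instance: id, name, class, centroid, z extent and flags.
#'
#' @param instances list of `vertebra_instance`.
#' @param path output path (tab-separated).
#' @return `path`, invisibly.
#' @export
write_instance_table <- function(instances, path) {
  df <- do.call(rbind, lapply(seq_along(instances), function(i) {
    x <- instances[[i]]
    data.frame(id = i, name = x$name, class = x$class_id,
               n_voxels = x$n_voxels,
               centroid_z = x$centroid[1], centroid_y = x$centroid[2],
               centroid_x = x$centroid[3],
               z_min = x$z_extent[1], z_max = x$z_extent[2],
               flags = paste(x$flags, collapse = ";"))
  }))
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
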