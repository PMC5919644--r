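## Accessors and show methods.

#' @name accessors
#' @title Accessors for TumorGrid and related objects
#' @description Slot access for the voxel lattice and dose plan classes.
#'   All per-voxel accessors return flat vectors over the full lattice in
#'   column-major (array) order.
#' @param object a [TumorGrid-class], [DosePlan-class] or [TCPResult-class]
NULL

#' @rdname accessors
#' @export
setGeneric("viableCells", function(object) standardGeneric("viableCells"))
#' @rdname accessors
#' @export
setMethod("viableCells", "TumorGrid", function(object) object@viable)

#' @rdname accessors
#' @export
setGeneric("deadCells", function(object) standardGeneric("deadCells"))
#' @rdname accessors
#' @export
setMethod("deadCells", "TumorGrid", function(object) object@dead)

#' @rdname accessors
#' @export
setGeneric("capillaryCells", function(object) standardGeneric("capillaryCells"))
#' @rdname accessors
#' @export
setMethod("capillaryCells", "TumorGrid", function(object) object@capillary)

#' Voxel capacity in cells
#'
#' All cell types share volume 1/mu, so a voxel holds at most
#' mu * voxelSide^3 cells (plus a transient proliferation headroom); the
#' value is fixed at grid construction.
#'
#' @param grid a [TumorGrid-class]
#' @return scalar capacity (cells per voxel)
#' @export
voxelCapacity <- function(grid) grid@capacity

#' @rdname accessors
#' @export
setGeneric("normalCells", function(object, ...) standardGeneric("normalCells"))
#' @param bio a [BioParams-class] giving the packing density
#' @rdname accessors
#' @export
setMethod("normalCells", "TumorGrid", function(object, ...) {
  pmax(0, object@capacity - object@viable - object@dead - object@capillary)
})

#' @rdname accessors
#' @export
setGeneric("tumorMask", function(object) standardGeneric("tumorMask"))
#' @rdname accessors
#' @export
setMethod("tumorMask", "TumorGrid", function(object) {
  object@viable + object@dead >= 1
})

#' Vascular fraction of each voxel
#'
#' vf = capillary / capacity: the fraction of the voxel volume occupied by
#' capillaries (the oxygen source density seen by the oxygenation model).
#'
#' @param object a [TumorGrid-class]
#' @return numeric vector over the lattice
#' @export
setGeneric("vascularFraction", function(object) standardGeneric("vascularFraction"))
#' @rdname vascularFraction
#' @export
setMethod("vascularFraction", "TumorGrid", function(object) {
  object@capillary / object@capacity
})

#' Consuming-cell volume fraction of each voxel
#'
#' s = viable / capacity: the fraction of the voxel volume occupied by
#' oxygen-consuming (viable) cells. At full packing this equals
#' 1 - dead fraction; it falls as cells are killed and resorbed, which is
#' the consumption side of treatment reoxygenation.
#'
#' @param object a [TumorGrid-class]
#' @return numeric vector over the lattice
#' @export
setGeneric("consumingFraction", function(object) standardGeneric("consumingFraction"))
#' @rdname consumingFraction
#' @export
setMethod("consumingFraction", "TumorGrid", function(object) {
  object@viable / object@capacity
})

#' Voxel center coordinates in mm relative to the lattice center
#'
#' @param grid a [TumorGrid-class]
#' @return nvoxel x 3 matrix of coordinates (mm)
#' @export
voxelCoordinates <- function(grid) {
  d <- grid@dims
  ctr <- (d + 1) / 2
  idx <- arrayInd(seq_len(prod(d)), d)
  sweep(idx, 2, ctr) * grid@voxelSide
}

#' Radial distance of each voxel from the lattice center (mm)
#' @param grid a [TumorGrid-class]
#' @return numeric vector (mm)
#' @export
voxelRadius <- function(grid) {
  xyz <- voxelCoordinates(grid)
  sqrt(rowSums(xyz^2))
}

#' Logical mask of the 1 cm diameter tumor core
#' @param grid a [TumorGrid-class]
#' @param coreDiameter core diameter (cm)
#' @return logical vector over the lattice
#' @export
coreMask <- function(grid, coreDiameter = 1) {
  voxelRadius(grid) <= coreDiameter * 10 / 2
}

#' Median pO2 of histograms
#'
#' The smallest bin center at which the cumulative weight reaches 0.5.
#'
#' @param object an [OxygenHistogram-class] or [TumorGrid-class]
#' @return median pO2 (mmHg); for grids, a vector over the lattice
#' @export
setGeneric("medianPO2", function(object) standardGeneric("medianPO2"))
#' @rdname medianPO2
#' @export
setMethod("medianPO2", "OxygenHistogram", function(object) {
  object@binCenters[which(cumsum(object@weights) >= 0.5)[1]]
})
#' @rdname medianPO2
#' @export
setMethod("medianPO2", "TumorGrid", function(object) {
  medianFromWeights(object@weights, object@binCenters)
})

## row-wise histogram median, vectorized over a weight matrix
medianFromWeights <- function(W, centers) {
  cw <- W
  for (j in seq(2, ncol(W))) cw[, j] <- cw[, j] + cw[, j - 1]
  idx <- max.col(cw >= 0.5, ties.method = "first")
  centers[idx]
}

#' @rdname accessors
#' @export
setGeneric("doses", function(object) standardGeneric("doses"))
#' @rdname accessors
#' @export
setMethod("doses", "DosePlan", function(object) object@doses)

#' @rdname accessors
#' @export
setGeneric("d50", function(object, ...) standardGeneric("d50"))

#' @rdname accessors
#' @export
setMethod("d50", "TCPResult", function(object) object@d50)

setMethod("show", "TumorGrid", function(object) {
  m <- tumorMask(object)
  cat("TumorGrid:", paste(object@dims, collapse = " x "),
      "lattice, voxel side", object@voxelSide, "mm\n")
  cat("  tumor voxels:", sum(m),
      "| viable cells:", format(sum(object@viable), digits = 4),
      "| dead:", format(sum(object@dead), digits = 4), "\n")
  if (any(m))
    cat("  vf range in mask:",
        paste(signif(range(vascularFraction(object)[m]), 3), collapse = " - "),
        "| time:", object@time, "h\n")
})

setMethod("show", "DosePlan", function(object) {
  d <- object@doses[!is.na(object@doses)]
  cat("DosePlan (", object@objective, "): ", length(d), " voxels, mean ",
      signif(mean(d), 6), " Gy, range [", signif(min(d), 4), ", ",
      signif(max(d), 4), "] Gy\n", sep = "")
})

setMethod("show", "OxygenHistogram", function(object) {
  cat("OxygenHistogram:", length(object@weights), "bins, median",
      signif(medianPO2(object), 3), "mmHg, mean",
      signif(sum(object@binCenters * object@weights), 3), "mmHg\n")
})

setMethod("show", "OxygenLookup", function(object) {
  cat("OxygenLookup:", length(object@vfGrid), "vf x", length(object@sGrid),
      "s nodes,", length(object@binCenters), "bins\n")
  cat("  vf:", paste(signif(range(object@vfGrid), 3), collapse = " - "),
      "| s:", paste(signif(range(object@sGrid), 3), collapse = " - "), "\n")
})

setMethod("show", "TCPResult", function(object) {
  cat("TCPResult [", object@scheme, "/", object@objective, "]: D50 = ",
      signif(object@d50, 4), " +/- ", signif(object@d50Uncertainty, 3),
      " Gy (k = 2)\n", sep = "")
  print(object@table, row.names = FALSE)
})

setMethod("show", "TreatmentSchedule", function(object) {
  cat("TreatmentSchedule:", object@scheme, "-", object@nFractions,
      "fractions over", max(object@fractionDays) + 1, "days;",
      length(object@optimizationFractions), "optimizations\n")
})
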