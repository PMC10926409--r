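#' @import methods
NULL

#' Accessor generics
#'
#' Small accessor generics shared by the package's S4 classes: calendar
#' dates, cell coordinate tables, per-cell weather matrices and raster
#' values.
#'
#' @param x an object of one of the package's S4 classes.
#' @return The slot content: a `Date` vector for `dates()`, a
#'   `data.frame` of cell coordinates for `cellCoords()`, a days-by-cells
#'   numeric matrix for `tmin()`, `tmax()` and `precip()`, a per-cell
#'   vector for `rasterValues()`, and a scalar for the remaining
#'   accessors.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("dates", function(x) standardGeneric("dates"))

#' @rdname accessors
#' @export
setGeneric("cellCoords", function(x) standardGeneric("cellCoords"))

#' @rdname accessors
#' @export
setGeneric("nCells", function(x) standardGeneric("nCells"))

#' @rdname accessors
#' @export
setGeneric("tmin", function(x) standardGeneric("tmin"))

#' @rdname accessors
#' @export
setGeneric("tmax", function(x) standardGeneric("tmax"))

#' @rdname accessors
#' @export
setGeneric("precip", function(x) standardGeneric("precip"))

#' @rdname accessors
#' @export
setGeneric("hasPrecip", function(x) standardGeneric("hasPrecip"))

#' @rdname accessors
#' @export
setGeneric("rasterValues", function(x) standardGeneric("rasterValues"))

#' @rdname accessors
#' @export
setGeneric("rasterMeaning", function(x) standardGeneric("rasterMeaning"))

#' @rdname accessors
#' @export
setGeneric("nYears", function(x) standardGeneric("nYears"))
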