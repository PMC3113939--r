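#' @rdname scaleRegion
#' @export
setGeneric("scaleRegion", function(r, factor) standardGeneric("scaleRegion"))

#' @rdname rasterize
#' @export
setGeneric("rasterize", function(r, width, height) standardGeneric("rasterize"))

#' Accessors for phenopipe objects
#'
#' Small accessor generics over the package's S4 classes: `configView()`,
#' `mmPerPx()`, `regionScale()`, `openingRadius()`, `objectClasses()` and
#' `sceneRegions()` read the slots of a [ViewConfig]; `classNames()` and
#' `labelMatrix()` read a [LabelImage]; `maskMatrix()` reads a [PlantMask].
#'
#' @param x a phenopipe object.
#' @return The corresponding slot value.
#' @name accessors
#' @examples
#' cfg <- defaultViewConfig("side")
#' configView(cfg)
#' mmPerPx(cfg)
NULL

#' @rdname accessors
#' @export
setGeneric("configView", function(x) standardGeneric("configView"))
#' @rdname accessors
#' @export
setGeneric("mmPerPx", function(x) standardGeneric("mmPerPx"))
#' @rdname accessors
#' @export
setGeneric("regionScale", function(x) standardGeneric("regionScale"))
#' @rdname accessors
#' @export
setGeneric("openingRadius", function(x) standardGeneric("openingRadius"))
#' @rdname accessors
#' @export
setGeneric("objectClasses", function(x) standardGeneric("objectClasses"))
#' @rdname accessors
#' @export
setGeneric("sceneRegions", function(x) standardGeneric("sceneRegions"))
#' @rdname accessors
#' @export
setGeneric("classNames", function(x) standardGeneric("classNames"))
#' @rdname accessors
#' @export
setGeneric("labelMatrix", function(x) standardGeneric("labelMatrix"))
#' @rdname accessors
#' @export
setGeneric("maskMatrix", function(x) standardGeneric("maskMatrix"))

#' @rdname accessors
setMethod("configView", "ViewConfig", function(x) x@view)
#' @rdname accessors
setMethod("mmPerPx", "ViewConfig", function(x) x@mmPerPx)
#' @rdname accessors
setMethod("regionScale", "ViewConfig", function(x) x@regionScale)
#' @rdname accessors
setMethod("openingRadius", "ViewConfig", function(x) as.integer(x@openingRadius))
#' @rdname accessors
setMethod("objectClasses", "ViewConfig", function(x) x@classes)
#' @rdname accessors
setMethod("sceneRegions", "ViewConfig", function(x) x@regions)
#' @rdname accessors
setMethod("classNames", "LabelImage", function(x) x@classNames)
#' @rdname accessors
setMethod("labelMatrix", "LabelImage", function(x) x@labels)
#' @rdname accessors
setMethod("maskMatrix", "PlantMask", function(x) x@mask)
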