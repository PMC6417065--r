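#' The canonical 55-feature registry
#'
#' Ordered names of the 55 radiomics features extracted per ROI:
#' size (1), first-order intensity statistics (8), gray level
#' co-occurrence matrix (15), gray level run length matrix (13), gray
#' level size zone matrix (13) and neighborhood gray tone difference
#' matrix (5).  `Volume` holds volume in mm^3 for 3D extraction and area
#' in mm^2 for 2D.  The same names are used for delta features and
#' signature coefficients.
#'
#' @param family optional family filter: one of "size", "firstorder",
#'   "glcm", "glrlm", "glszm", "ngtdm".
#' @return character vector of feature names, in registry order.
#' @export
feature_registry <- function(family = NULL) {
  fam <- list(
    size = "Volume",
    firstorder = paste0("Int_", c("Mean", "Median", "StdDev", "Skewness",
                                  "Kurtosis", "Energy", "Entropy",
                                  "Uniformity")),
    glcm = paste0("GLCM_", c("Energy", "Contrast", "Correlation",
                             "SumAverage", "SumVariance", "SumEntropy",
                             "Entropy", "DifferenceVariance",
                             "DifferenceEntropy",
                             "InverseDifferenceMoment", "Autocorrelation",
                             "ClusterShade", "ClusterProminence",
                             "Dissimilarity", "MaximumProbability")),
    glrlm = paste0("GLRLM_", c("SRE", "LRE", "GLN", "RLN", "RunPercentage",
                               "LGLRE", "HGLRE", "SRLGLE", "SRHGLE",
                               "LRLGLE", "LRHGLE", "GrayLevelVariance",
                               "RunLengthVariance")),
    glszm = paste0("GLSZM_", c("SAE", "LAE", "GLN", "ZSN", "ZonePercentage",
                               "LGLZE", "HGLZE", "SALGLE", "SAHGLE",
                               "LZLGLE", "LZHGLE", "GrayLevelVariance",
                               "ZoneSizeVariance")),
    ngtdm = paste0("NGTDM_", c("Coarseness", "Contrast", "Busyness",
                               "Complexity", "Strength")))
  if (is.null(family)) return(unname(unlist(fam)))
  if (!family %in% names(fam)) stop("unknown feature family: ", family)
  fam[[family]]
}

# Half neighborhoods used as displacement sets: 13 unique directions in
# 3D (half of the 26-neighborhood), 4 in 2D (half of 8).  Rows (dz,dy,dx).
direction_set <- function(dims) {
  g <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  first_nonzero_pos <- apply(g, 1, function(r) r[which(r != 0)[1]] > 0)
  g <- g[first_nonzero_pos, , drop = FALSE]          # 13 unique directions
  if (dims == "2D") g <- g[g[, "dz"] == 0, , drop = FALSE]  # 4 in-plane
  storage.mode(g) <- "integer"
  unname(g)
}

full_neighborhood <- function(dims) {
  h <- direction_set(dims)
  rbind(h, -h)
}
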