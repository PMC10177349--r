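Package: grazeRF
Title: Livestock Residency Indices and Random-Forest Grazing-Driver Models
    from GPS Collar Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing livestock GPS collar trajectories in fenced
    paddocks: quality-control and cleaning of burst-scheduled fixes,
    movement metrics (step distances, speeds, activity summaries, behaviour
    recoding), a gridded Livestock Residency Index (LRI) on a 5 m paddock
    grid, assembly of a 12-predictor landscape and weather covariate table
    (near distances to trees, water troughs and fences; elevation, aspect,
    NDVI; temperature, rainfall and a sheep chill index; coordinates and
    animal identity), and random-forest models of residency with
    out-of-bag performance, permutation-based importance significance and
    partial-dependence curves. A seeded simulation module generates
    paddock landscapes, weather and flock trajectories with known driver
    weights so the whole pipeline can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    ranger,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    rpart,
    car
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'covariates.R'
    'driver-model.R'
    'geojson.R'
    'geometry.R'
    'grazeRF-package.R'
    'movement.R'
    'raster.R'
    'residency.R'
    'synthetic.R'
    'trajectory.R'
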