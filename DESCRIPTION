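Package: walkdist
Title: Total Walk Distance from Foot-Worn Inertial Sensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the total distance walked during standardized walking
    tests (400 m walk, six-minute walk test) from foot-mounted inertial
    measurement units. Implements quaternion orientation fusion of gyroscope
    and accelerometer signals, Earth-frame gravity removal, zero-velocity
    update (ZUPT) dead reckoning with linear velocity de-drifting, per-stride
    horizontal chord distances summed over the walk with bilateral averaging,
    and the agreement statistics used to validate such algorithms against
    manual distance (absolute error rates, Bland-Altman limits of agreement,
    ICC(2,1)). Includes a forward gait simulator with an inverse sensor model
    that generates synthetic IMU recordings with known ground truth, so the
    whole pipeline is testable without hardware data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
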