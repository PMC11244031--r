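[
  {
    "abbreviation": "NDVI",
    "name": "Normalized Difference Vegetation Index",
    "wavelengths": [860, 680],
    "expression": "(r860 - r680) / (r860 + r680)"
  },
  {
    "abbreviation": "BGI2",
    "name": "Blue Green Pigment Index 2",
    "wavelengths": [450, 550],
    "expression": "r450 / r550"
  },
  {
    "abbreviation": "RDVI",
    "name": "Renormalized Difference Vegetation Index",
    "wavelengths": [860, 680],
    "expression": "(r860 - r680) / sqrt(r860 + r680)"
  },
  {
    "abbreviation": "TCARI",
    "name": "Transformed Chlorophyll Absorption in Reflectance Index",
    "wavelengths": [700, 680, 550],
    "expression": "3 * ((r700 - r680) - 0.2 * (r700 - r550) * (r700 / r680))"
  },
  {
    "abbreviation": "GOSAVI",
    "name": "Green Optimized Soil Adjusted Vegetation Index",
    "wavelengths": [860, 550],
    "expression": "(r860 - r550) / (r860 + r550 + 0.16)"
  },
  {
    "abbreviation": "TCARIOSAVI",
    "name": "TCARI/GOSAVI Ratio",
    "wavelengths": [700, 680, 550, 860],
    "expression": "(3 * ((r700 - r680) - 0.2 * (r700 - r550) * (r700 / r680))) / ((r860 - r550) / (r860 + r550 + 0.16))"
  },
  {
    "abbreviation": "MCARI2",
    "name": "Modified Chlorophyll Absorption in Reflectance Index 2",
    "wavelengths": [860, 680, 550],
    "expression": "1.5 * (2.5 * (r860 - r680) - 1.3 * (r860 - r550)) / sqrt((2 * r860 + 1)^2 - (6 * r860 - 5 * sqrt(r680)) - 0.5)"
  },
  {
    "abbreviation": "PRI",
    "name": "Photochemical Reflectance Index",
    "wavelengths": [531, 570],
    "expression": "(r531 - r570) / (r531 + r570)"
  },
  {
    "abbreviation": "TDVI",
    "name": "Transformed Difference Vegetation Index",
    "wavelengths": [860, 680],
    "expression": "1.5 * (r860 - r680) / sqrt(r860^2 + r680 + 0.5)"
  },
  {
    "abbreviation": "CRI2",
    "name": "Carotenoid Reflectance Index 2",
    "wavelengths": [510, 700],
    "expression": "1 / r510 - 1 / r700"
  },
  {
    "abbreviation": "PSRI",
    "name": "Plant Senescing Reflectance Index",
    "wavelengths": [680, 450, 750],
    "expression": "(r680 - r450) / r750"
  },
  {
    "abbreviation": "GLI",
    "name": "Green Leaf Index",
    "wavelengths": [550, 680, 450],
    "expression": "(2 * r550 - r680 - r450) / (2 * r550 + r680 + r450)"
  },
  {
    "abbreviation": "RENDVI",
    "name": "Red Edge Normalized Difference Vegetation Index",
    "wavelengths": [750, 700],
    "expression": "(r750 - r700) / (r750 + r700)"
  },
  {
    "abbreviation": "SIPI",
    "name": "Structure Insensitive Pigment Index",
    "wavelengths": [860, 445, 680],
    "expression": "(r860 - r445) / (r860 + r680)"
  },
  {
    "abbreviation": "NLI",
    "name": "Nonlinear Vegetation Index",
    "wavelengths": [860, 680],
    "expression": "(r860^2 - r680) / (r860^2 + r680)"
  }
]
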