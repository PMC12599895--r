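GLCM_Correlation_0_D1
GLCM_Correlation_45_D1
GLCM_Correlation_90_D1
GLCM_Correlation_135_D1
GLCM_Correlation_Mean_D1
GLCM_Correlation_STD_D1
GLCM_Correlation_0_D2
GLCM_Correlation_45_D2
GLCM_Correlation_90_D2
GLCM_Correlation_135_D2
GLCM_Correlation_Mean_D2
GLCM_Correlation_STD_D2
GLCM_Correlation_0_D3
GLCM_Correlation_45_D3
GLCM_Correlation_90_D3
GLCM_Correlation_135_D3
GLCM_Correlation_Mean_D3
GLCM_Correlation_STD_D3
GLCM_Contrast_0_D1
GLCM_Contrast_45_D1
GLCM_Contrast_90_D1
GLCM_Contrast_135_D1
GLCM_Contrast_Mean_D1
GLCM_Contrast_STD_D1
GLCM_Contrast_0_D2
GLCM_Contrast_45_D2
GLCM_Contrast_90_D2
GLCM_Contrast_135_D2
GLCM_Contrast_Mean_D2
GLCM_Contrast_STD_D2
GLCM_Contrast_0_D3
GLCM_Contrast_45_D3
GLCM_Contrast_90_D3
GLCM_Contrast_135_D3
GLCM_Contrast_Mean_D3
GLCM_Contrast_STD_D3
GLCM_Energy_0_D1
GLCM_Energy_45_D1
GLCM_Energy_90_D1
GLCM_Energy_135_D1
GLCM_Energy_Mean_D1
GLCM_Energy_STD_D1
GLCM_Energy_0_D2
GLCM_Energy_45_D2
GLCM_Energy_90_D2
GLCM_Energy_135_D2
GLCM_Energy_Mean_D2
GLCM_Energy_STD_D2
GLCM_Energy_0_D3
GLCM_Energy_45_D3
GLCM_Energy_90_D3
GLCM_Energy_135_D3
GLCM_Energy_Mean_D3
GLCM_Energy_STD_D3
GLCM_Homogeneity_0_D1
GLCM_Homogeneity_45_D1
GLCM_Homogeneity_90_D1
GLCM_Homogeneity_135_D1
GLCM_Homogeneity_Mean_D1
GLCM_Homogeneity_STD_D1
GLCM_Homogeneity_0_D2
GLCM_Homogeneity_45_D2
GLCM_Homogeneity_90_D2
GLCM_Homogeneity_135_D2
GLCM_Homogeneity_Mean_D2
GLCM_Homogeneity_STD_D2
GLCM_Homogeneity_0_D3
GLCM_Homogeneity_45_D3
GLCM_Homogeneity_90_D3
GLCM_Homogeneity_135_D3
GLCM_Homogeneity_Mean_D3
GLCM_Homogeneity_STD_D3
FOS_Mean
FOS_STD
FOS_Variance
FOS_Skewness
FOS_Kurtosis
FOS_Entropy
FOS_Energy
FOS_Median
FOS_P01
FOS_P99
Intensity_Maximum
Intensity_Mean
Intensity_Minimum
Intensity_Range
Shape_Area
Shape_Perimeter
Shape_MajorAxisLength
Shape_MinorAxisLength
Shape_Eccentricity
Shape_Orientation
Shape_EquivDiameter
Shape_Extent
Shape_ConvexArea
Shape_FilledArea
Shape_Solidity
Shape_Circularity
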