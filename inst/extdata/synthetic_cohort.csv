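"patient","response","progression","superscan","m_vol_ml","inv_percent","psa_ng_ml","lesion_count","b_counts","m_counts","b_hu","m_hu"
"PD_1","PD",TRUE,FALSE,540.04,0.5,174.06,26,361.45,793.54,202.68,343.81
"PD_2","PD",TRUE,FALSE,140.56,14.74,63.35,28,380.44,627.24,328.39,570.82
"PD_3","PD",TRUE,FALSE,0,9.53,32.6,89,322.96,605.61,293.16,513.01
"PD_4","PD",TRUE,FALSE,224.87,30.47,447.21,39,327.8,760.82,168.24,470.3
"PD_5","PD",TRUE,FALSE,374.35,46.91,534.98,107,315.18,936.95,331.2,458.44
"PD_6","PD",TRUE,FALSE,139.29,0.5,158.24,53,322.38,417.33,220.81,618.37
"PD_7","PD",TRUE,FALSE,0,12.8,1,92,232.47,777.9,275.92,652.23
"PD_8","PD",TRUE,FALSE,81.18,16.74,62.92,41,204.1,546.47,281.8,506.91
"PD_9","PD",TRUE,FALSE,0,0.5,1,58,236.3,828.16,171.22,267.61
"PD_10","PD",TRUE,FALSE,0,0.5,341.16,56,210.7,789.24,222.27,470.13
"PD_11","PD",TRUE,TRUE,0,68.57,2274.02,158,220.78,634.42,284.37,440.35
"PD_12","PD",TRUE,FALSE,122.87,44.05,182.04,20,242.54,625.34,214.94,577.46
"PD_13","PD",TRUE,FALSE,21.32,49.12,1,5,220.83,595.09,296.94,715.1
"PD_14","PD",TRUE,TRUE,429.61,58.38,409.84,135,341.42,675.37,151.38,516.08
"PD_15","PD",TRUE,FALSE,750.2,35.08,355.15,66,359.17,433.84,213.63,432.52
"PD_16","PD",TRUE,FALSE,0,31.71,446.35,23,331.49,780.78,229.81,409.91
"PD_17","PD",TRUE,TRUE,85.02,58.16,252.03,87,370.99,798.83,238.79,582.86
"PD_18","PD",TRUE,FALSE,161.89,9.66,803.01,89,370.95,813.11,201.78,618.04
"PD_19","PD",TRUE,FALSE,0,2.09,500.13,83,237.76,313.37,333,384.08
"PD_20","PD",TRUE,FALSE,0,10.68,174.63,80,382.9,709.7,287.18,755.62
"PD_21","PD",TRUE,FALSE,632.52,3.85,171.85,84,256.97,1115.69,323.86,638.79
"SD_1","SD",FALSE,FALSE,300.91,6.54,150.41,67,415.71,1389.85,270.62,783.5
"SD_2","SD",FALSE,TRUE,299.53,27.56,3061.77,96,673.15,1109.83,193.97,795.17
"SD_3","SD",FALSE,TRUE,288.84,19.24,1402.44,119,215.09,637.7,199.12,430.16
"SD_4","SD",FALSE,FALSE,728.69,38.71,143.37,84,213.2,832.39,273.6,510.24
"SD_5","SD",FALSE,FALSE,377.44,43.45,1,51,642.92,1366.19,358.01,589.58
"SD_6","SD",FALSE,FALSE,285.33,36.06,552,40,463.82,1300.89,285.82,615.07
"SD_7","SD",FALSE,FALSE,156.4,46.6,450.97,56,498.89,1270.96,156.46,697.4
"SD_8","SD",FALSE,FALSE,489.14,46.59,1,60,317.91,1311.19,313.41,767.76
"SD_9","SD",FALSE,FALSE,438.75,11.07,1,86,373.53,1120.6,216.79,730.35
"SD_10","SD",FALSE,FALSE,107.58,49.77,731.47,71,358.89,936.37,297.78,396.14
"SD_11","SD",FALSE,FALSE,94.29,16.19,1,39,405.38,1208.76,323.27,578.77
"SD_12","SD",FALSE,TRUE,578.65,49.51,1518.48,96,564.44,1313.38,235.48,591.61
"SD_13","SD",FALSE,TRUE,214.27,29.38,1743.09,101,359.41,950.08,205.13,573.14
"SD_14","SD",FALSE,FALSE,402.01,11.79,288.61,63,739.33,823.43,175.08,571.9
"SD_15","SD",FALSE,FALSE,449.55,24.86,147.44,54,384.51,1007.32,329.86,887.14
"SD_16","SD",FALSE,FALSE,357.77,39.69,1,76,344.63,1045.74,235.88,558.06
"SD_17","SD",FALSE,FALSE,287.36,0.5,155.91,31,402.22,1340.51,181.83,431.65
"SD_18","SD",FALSE,FALSE,134.28,26.3,713.14,87,237.27,1172.75,327.38,524
"SD_19","SD",FALSE,FALSE,291.58,6.81,1,72,695.04,815.8,180.89,519.67
"SD_20","SD",FALSE,FALSE,569.51,30.53,625.22,81,795.07,944.1,287.57,281.56
"SD_21","SD",FALSE,FALSE,94.82,27.25,486.29,51,532.67,996.99,326.84,549.71
"SD_22","SD",FALSE,FALSE,525.66,14.21,1,88,705.32,1083.26,300.75,712.37
"SD_23","SD",FALSE,FALSE,456.37,13.45,1,89,281.48,980.92,346.43,788.55
"SD_24","SD",FALSE,FALSE,163.8,10.9,1,80,295.07,1228.78,242.19,735.55
"SD_25","SD",FALSE,FALSE,62.71,17.66,1,88,723.74,722.78,249.8,533.54
"SD_26","SD",FALSE,TRUE,29.26,5.97,1379.56,85,369.79,1345.51,277.68,748.65
"SD_27","SD",FALSE,FALSE,0,26.54,553.84,105,849.89,1177.78,263.45,647.46
"SD_28","SD",FALSE,FALSE,372.6,28.06,237.34,67,469.28,1281.37,165.29,679.43
"SD_29","SD",FALSE,FALSE,490.05,29.26,442.81,41,746.79,950.56,272.77,600.52
"SD_30","SD",FALSE,FALSE,332.19,0.5,1144.78,43,387.22,1360.57,292.03,489.08
"SD_31","SD",FALSE,FALSE,434.68,20.55,457.32,68,510.39,1369.94,181.76,687.75
"SD_32","SD",FALSE,FALSE,784.8,54.74,782.98,97,493.85,1272.6,258.63,614.17
"SD_33","SD",FALSE,TRUE,441.91,31.67,982.65,117,912,1353.97,205,845.31
"SD_34","SD",FALSE,FALSE,604.34,40.04,1,28,240.75,815.24,194.53,624.14
"SD_35","SD",FALSE,FALSE,288.58,33.08,621.67,81,132.53,1547.06,367.09,869.78
"PR_1","PR",FALSE,FALSE,400.46,8.4,1,49,333.49,815.46,301.97,792.3
"PR_2","PR",FALSE,TRUE,314.2,68.17,1,120,415.4,610.19,335.4,573.83
"PR_3","PR",FALSE,FALSE,402.82,18.79,545.72,85,742.02,1079.2,486.54,682
"PR_4","PR",FALSE,FALSE,325.26,29.68,95.77,55,180.16,946.08,470.33,516.76
"PR_5","PR",FALSE,FALSE,9.52,30.84,183.88,45,355.47,946.6,279.35,549.56
"PR_6","PR",FALSE,FALSE,427.02,8.99,1,35,378.1,1118.03,185.48,717.54
"PR_7","PR",FALSE,FALSE,690.13,19.08,1,87,787.27,441.72,286.89,357.63
"PR_8","PR",FALSE,FALSE,16.15,31.35,1,55,919.1,1120.87,201.02,520.5
"PR_9","PR",FALSE,FALSE,0,17.63,1,37,411.13,793.12,287,645.61
"PR_10","PR",FALSE,FALSE,537.26,33.83,348.55,86,354.64,972.97,343.15,664.43
"PR_11","PR",FALSE,FALSE,298.68,5.07,1,37,584.6,1474.53,87.54,512.37
"PR_12","PR",FALSE,TRUE,338.87,34.78,2486.02,117,413.59,1143.15,239.11,663.13
"PR_13","PR",FALSE,FALSE,221.99,20.57,1,86,624.51,1088.79,264.08,218.77
"PR_14","PR",FALSE,TRUE,382.17,41.93,149.51,121,571.69,564.28,152.32,376.19
"PR_15","PR",FALSE,FALSE,662.53,15.03,1,93,608.91,758.65,273.15,379.07
"PR_16","PR",FALSE,FALSE,40.29,40.95,1,57,561.09,943.38,382.14,536.45
"PR_17","PR",FALSE,FALSE,0,31.9,676.65,60,671.54,796.75,280.58,774.63
"PR_18","PR",FALSE,FALSE,139.99,39.14,927.97,69,434.88,765.44,284.78,579.51
"PR_19","PR",FALSE,FALSE,690.7,0.5,268.74,65,249.83,1096.98,286.59,849.04
"PR_20","PR",FALSE,FALSE,408.35,23.63,702.49,31,288.75,709.78,243.05,497.96
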