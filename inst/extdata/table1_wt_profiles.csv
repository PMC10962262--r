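group,Speed_p1_6,M_1h,M_Accl,M_Vis,M_St,M_Hab_7_9,M_Hab_9_11,E_1h,E_Accl,E_Vis,E_St,E_Hab_7_9,E_Hab_9_11,CW_p1_6,OMRL_7_8,OMRL_9_10,OMRL_11_12,OMRLHab_7_9,OMRLHab_9_11,OMRO_7_8,OMRO_9_10,OMRO_11_12,OMROHab_7_9,OMROHab_9_11
WT,3.327608132,55%,0%,60%,−5%,−7%,3%,62%,−1%,84%,−28%,15%,1%,54%,−96%,−30%,−64%,26%,0%,−24%,−12%,−22%,5%,−6%
WT,2.830924367,41%,−2%,59%,−19%,−5%,2%,67%,8%,79%,−30%,13%,9%,41%,−92%,−63%,−57%,11%,−2%,−37%,−34%,−25%,3%,8%
WT,2.48269152,30%,25%,51%,−53%,5%,23%,57%,−8%,77%,−32%,26%,0%,49%,−91%,26%,54%,42%,25%,−38%,−5%,5%,7%,5%
WT,2.207779949,23%,−2%,60%,−23%,−8%,−8%,60%,−10%,68%,−13%,12%,13%,49%,−83%,−75%,−10%,9%,−2%,−28%,−19%,−13%,5%,3%
WT,3.08552068,43%,3%,70%,−26%,−36%,6%,69%,15%,80%,5%,6%,5%,60%,−86%,−73%,−40%,6%,3%,−12%,−24%,−6%,−5%,8%
WT,2.81435937,41%,0%,70%,−55%,−9%,9%,77%,−5%,78%,−3%,33%,−3%,59%,−94%,−38%,−42%,55%,0%,−29%,−17%,−16%,12%,−2%
WT,1.437875412,14%,−1%,67%,−61%,−6%,14%,62%,−14%,69%,−25%,29%,8%,22%,−92%,−75%,−48%,10%,−1%,−51%,−23%,1%,18%,8%
WT,2.577432247,35%,11%,63%,−37%,6%,5%,61%,0%,65%,−3%,0%,−4%,49%,−29%,−18%,2%,13%,11%,−9%,−12%,−5%,−1%,7%
WT,2.440140508,26%,12%,25%,−10%,46%,−6%,44%,8%,79%,−37%,−16%,22%,50%,47%,−33%,−65%,−82%,28%,27%,−21%,−38%,−48%,15%
WT,2.625247097,38%,11%,29%,−50%,66%,−7%,68%,−10%,75%,−12%,−9%,−5%,47%,−44%,−18%,−57%,25%,−40%,−24%,−23%,−21%,−1%,0%
WT,2.892485765,34%,11%,26%,−27%,41%,−8%,58%,−13%,65%,−39%,48%,−4%,64%,−85%,−15%,−14%,67%,−13%,−51%,−16%,−4%,30%,8%
WT,3.295731215,55%,1%,34%,−62%,78%,−7%,49%,17%,62%,16%,3%,−12%,72%,−79%,−42%,−41%,30%,−5%,−9%,−16%,−17%,−7%,6%
WT,3.854794279,63%,4%,31%,−44%,66%,−11%,64%,3%,67%,−13%,27%,−4%,51%,−86%,−39%,−9%,28%,11%,−26%,−7%,−13%,12%,−2%
WT,3.569697566,55%,−3%,28%,−10%,58%,−6%,74%,−6%,76%,−15%,26%,−14%,52%,−84%,−8%,−26%,71%,−14%,−37%,−6%,3%,17%,9%
WT,5.812450811,70%,0%,34%,3%,60%,−8%,80%,−11%,73%,−16%,34%,−15%,52%,−73%,13%,−8%,68%,−17%,−34%,2%,−13%,28%,−12%
WT,3.4106223,53%,−9%,30%,−38%,72%,−8%,81%,5%,84%,8%,−13%,20%,52%,−85%,−33%,13%,52%,11%,−18%,2%,1%,14%,−17%
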